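#' Cost configuration
#'
#' One document holding every model parameter: wage profile, activity
#' timing, PPE catalogue, equipment profile, staffing scenarios, and
#' options. The defaults are the 2020 CVM program parameter set, so
#' `cost_config()` with no arguments prices that program.
#'
#' `options`:
#' * `equipment_total_override` — optional dollar total that replaces the
#'   computed `monitored days x per-day cost` program cost (used when a
#'   program's bookkept equipment expense is known directly).
#' * `roi_sig_figs` — significant figures for reported ROI (default 3).
#'
#' @param wage A [wage_profile()].
#' @param timing An [activity_timing()].
#' @param ppe A PPE catalogue tibble ([default_ppe_catalogue()]).
#' @param equipment An [equipment_profile()].
#' @param scenarios List of [staffing_scenario()] objects.
#' @param options List with `equipment_total_override` and `roi_sig_figs`.
#' @return A `cvm_config` object.
#' @examples
#' cfg <- default_config()
#' kit_cost_per_change(cfg$ppe)  # 9.78
#' @export
cost_config <- function(wage = wage_profile(),
                        timing = activity_timing(),
                        ppe = default_ppe_catalogue(),
                        equipment = equipment_profile(),
                        scenarios = default_scenarios(),
                        options = list()) {
  stopifnot(inherits(wage, "cvm_wage_profile"),
            inherits(timing, "cvm_activity_timing"),
            inherits(equipment, "cvm_equipment_profile"))
  validate_ppe_catalogue(ppe)
  if (inherits(scenarios, "cvm_staffing_scenario")) scenarios <- list(scenarios)
  for (s in scenarios) {
    if (!inherits(s, "cvm_staffing_scenario")) {
      abort_invalid("`scenarios` must be a list of staffing_scenario objects",
                    field = "scenarios")
    }
  }
  opts <- list(equipment_total_override = NULL, roi_sig_figs = 3)
  unknown <- setdiff(names(options), names(opts))
  if (length(unknown)) {
    abort_invalid(paste0("unknown option(s): ", paste(unknown, collapse = ", ")),
                  field = "options")
  }
  opts[names(options)] <- options
  if (!is.null(opts$equipment_total_override)) {
    opts$equipment_total_override <-
      check_number(opts$equipment_total_override, "equipment_total_override", min = 0)
  }
  opts$roi_sig_figs <- check_number(opts$roi_sig_figs, "roi_sig_figs",
                                    min = 1, integer = TRUE)
  structure(
    list(wage = wage, timing = timing, ppe = ppe, equipment = equipment,
         scenarios = scenarios, options = opts),
    class = "cvm_config"
  )
}

#' @rdname cost_config
#' @export
default_config <- function() {
  cost_config()
}

#' @rdname cost_config
#' @export
default_scenarios <- function() {
  list(staffing_scenario("added monitor staffing", hourly_rate = 15,
                         fte_added = 0.5, hours_per_day = 24, n_days = 270))
}

#' @export
print.cvm_config <- function(x, ...) {
  cat("<cvm cost configuration>\n")
  print(x$wage)
  print(x$timing)
  cat(sprintf("<ppe catalogue> %d categories, %s per PPE change\n",
              length(unique(x$ppe$category)), fmt_dollars(kit_cost_cents(x$ppe))))
  print(x$equipment)
  for (s in x$scenarios) print(s)
  if (!is.null(x$options$equipment_total_override)) {
    cat(sprintf("  equipment total override: %s\n",
                fmt_dollars(cents(x$options$equipment_total_override))))
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

config_to_list <- function(config) {
  ppe_list <- purrr::map(
    split(seq_len(nrow(config$ppe)),
          factor(config$ppe$category, unique(config$ppe$category))),
    function(i) {
      rows <- config$ppe[i, ]
      mode <- rows$mode[[1]]
      out <- list(category = rows$category[[1]], mode = mode)
      if (mode == "mixed_variants") {
        out$variants <- purrr::pmap(
          list(rows$variant, rows$usage_rate, rows$unit_cost),
          function(v, r, c) list(name = v, usage_rate = r, unit_cost = c)
        )
      } else {
        out$unit_cost <- rows$unit_cost[[1]]
        if (mode == "reusable") out$uses_per_unit <- rows$uses_per_unit[[1]]
      }
      out
    }
  )
  list(
    wage = unclass(config$wage),
    timing = config$timing[c("don_minutes", "doff_minutes")],
    ppe = unname(ppe_list),
    equipment = unclass(config$equipment),
    scenarios = purrr::map(config$scenarios, ~ unclass(.x)),
    options = config$options
  )
}

ppe_from_list <- function(ppe, path = "/ppe") {
  rows <- purrr::imap_dfr(ppe, function(cat, i) {
    p <- sprintf("%s/%d", path, i)
    unknown <- setdiff(names(cat),
                       c("category", "mode", "variants", "unit_cost", "uses_per_unit"))
    if (length(unknown)) {
      abort_invalid(sprintf("unknown key at %s/%s", p, unknown[[1]]), field = p)
    }
    if (is.null(cat$category) || is.null(cat$mode)) {
      abort_invalid(sprintf("%s: `category` and `mode` are required", p), field = p)
    }
    if (identical(cat$mode, "mixed_variants")) {
      if (is.null(cat$variants)) {
        abort_invalid(sprintf("%s: mixed_variants requires `variants`", p), field = p)
      }
      purrr::imap_dfr(cat$variants, function(v, j) {
        vp <- sprintf("%s/variants/%d", p, j)
        unknown <- setdiff(names(v), c("name", "usage_rate", "unit_cost"))
        if (length(unknown)) {
          abort_invalid(sprintf("unknown key at %s/%s", vp, unknown[[1]]), field = vp)
        }
        tibble::tibble(category = cat$category, mode = cat$mode,
                       variant = v$name %||% NA_character_,
                       usage_rate = as.numeric(v$usage_rate %||% NA),
                       unit_cost = as.numeric(v$unit_cost %||% NA),
                       uses_per_unit = NA_real_)
      })
    } else {
      tibble::tibble(category = cat$category, mode = cat$mode, variant = NA_character_,
                     usage_rate = NA_real_,
                     unit_cost = as.numeric(cat$unit_cost %||% NA),
                     uses_per_unit = as.numeric(cat$uses_per_unit %||% NA))
    }
  })
  validate_ppe_catalogue(rows)
  rows
}

merge_section <- function(defaults, given, section, allowed) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown)) {
    abort_invalid(sprintf("unknown key at /%s/%s", section, unknown[[1]]),
                  field = paste0(section, "/", unknown[[1]]))
  }
  defaults[names(given)] <- given
  defaults
}

config_from_list <- function(doc) {
  if (is.null(doc)) doc <- list()
  sections <- c("wage", "timing", "ppe", "equipment", "scenarios", "options")
  unknown <- setdiff(names(doc), sections)
  if (length(unknown)) {
    abort_invalid(sprintf("unknown key at /%s", unknown[[1]]), field = unknown[[1]])
  }
  overridden <- names(doc)

  wage_args <- merge_section(
    list(base_hourly_rate = 45, fringe_fraction = 0.30, productivity_fraction = 0.80),
    doc$wage, "wage",
    c("base_hourly_rate", "fringe_fraction", "productivity_fraction"))
  timing_args <- merge_section(
    list(don_minutes = 4, doff_minutes = 6),
    doc$timing, "timing", c("don_minutes", "doff_minutes"))
  equip_args <- merge_section(
    list(purchase_cost = 4500, amortization_years = 3, days_per_year = 365,
         cleaning_cost_per_day = 10),
    doc$equipment, "equipment",
    c("purchase_cost", "amortization_years", "days_per_year", "cleaning_cost_per_day"))
  opt_args <- merge_section(
    list(equipment_total_override = NULL, roi_sig_figs = 3),
    doc$options, "options", c("equipment_total_override", "roi_sig_figs"))

  ppe <- if (is.null(doc$ppe)) default_ppe_catalogue() else ppe_from_list(doc$ppe)
  scenarios <- if (is.null(doc$scenarios)) {
    default_scenarios()
  } else {
    purrr::imap(doc$scenarios, function(s, i) {
      p <- sprintf("/scenarios/%d", i)
      unknown <- setdiff(names(s), c("label", "hourly_rate", "added_hours",
                                     "fte_added", "hours_per_day", "n_days"))
      if (length(unknown)) {
        abort_invalid(sprintf("unknown key at %s/%s", p, unknown[[1]]), field = p)
      }
      rlang::exec(staffing_scenario, !!!s)
    })
  }

  cfg <- cost_config(
    wage = rlang::exec(wage_profile, !!!wage_args),
    timing = rlang::exec(activity_timing, !!!timing_args),
    ppe = ppe,
    equipment = rlang::exec(equipment_profile, !!!equip_args),
    scenarios = scenarios,
    options = opt_args
  )
  attr(cfg, "overridden_sections") <- overridden
  cfg
}

#' Read and write cost configurations
#'
#' Configurations are YAML or JSON documents (chosen by file extension:
#' `.json` for JSON, anything else parsed as YAML) against one schema.
#' Omitted fields take the 2020 program defaults; unknown keys are
#' rejected with the path to the offending key. An empty document yields
#' the full default configuration. `wage`, `timing`, `equipment` and
#' `options` merge key-by-key onto the defaults; `ppe` and `scenarios`
#' replace the default blocks wholesale when present.
#'
#' @param path File path.
#' @param config A `cvm_config` to serialize.
#' @return `load_config()` a validated `cvm_config`; `write_config()` the
#'   path, invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_config(default_config(), p)
#' identical(config_digest(load_config(p)), config_digest(default_config()))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_invalid(sprintf("config file not found: %s", path), field = "path")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(doc)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cvm_config"))
  doc <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname load_config
#' @export
config_digest <- function(config) {
  # canonical plain-list form, convenient for identity checks
  config_to_list(config)
}

# ---- parameter paths (used by one_way_sweep and the CLI) -------------------

#' Set a numeric configuration leaf by dotted path
#'
#' Paths address scalar leaves: `"wage.base_hourly_rate"`,
#' `"timing.don_minutes"`, `"equipment.cleaning_cost_per_day"`,
#' `"options.roi_sig_figs"`; PPE leaves as
#' `"ppe.<category>.unit_cost"` / `"ppe.<category>.uses_per_unit"` for
#' simple and reusable categories, or `"ppe.<category>.<variant>.unit_cost"`
#' (also `.usage_rate`) for mixed-variant categories. The returned
#' configuration is re-validated; the input is never mutated.
#'
#' @param config A `cvm_config`.
#' @param path Dotted parameter path.
#' @param value New numeric value.
#' @return A new `cvm_config`.
#' @examples
#' cfg <- set_config_value(default_config(), "ppe.masks.N95.unit_cost", 2.00)
#' kit_cost_per_change(cfg$ppe)  # 7.16
#' @export
set_config_value <- function(config, path, value) {
  stopifnot(inherits(config, "cvm_config"))
  value <- check_number(value, path)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  bad_path <- function() {
    abort_invalid(sprintf("cannot resolve parameter path '%s'", path), field = path)
  }
  if (length(parts) < 2) bad_path()
  section <- parts[[1]]

  if (section %in% c("wage", "timing", "equipment", "options")) {
    if (length(parts) != 2) bad_path()
    obj <- config[[section]]
    if (!parts[[2]] %in% names(obj)) bad_path()
    obj[[parts[[2]]]] <- value
    rebuilt <- switch(section,
      wage = rlang::exec(wage_profile, !!!unclass(obj)),
      timing = rlang::exec(activity_timing,
                           don_minutes = obj$don_minutes, doff_minutes = obj$doff_minutes),
      equipment = rlang::exec(equipment_profile, !!!unclass(obj)),
      options = obj
    )
    args <- list(wage = config$wage, timing = config$timing, ppe = config$ppe,
                 equipment = config$equipment, scenarios = config$scenarios,
                 options = config$options)
    args[[section]] <- rebuilt
    return(rlang::exec(cost_config, !!!args))
  }

  if (section == "ppe") {
    ppe <- config$ppe
    field <- parts[[length(parts)]]
    if (!field %in% c("unit_cost", "usage_rate", "uses_per_unit")) bad_path()
    if (length(parts) == 3) {
      i <- which(ppe$category == parts[[2]])
      if (length(i) != 1) bad_path()
    } else if (length(parts) == 4) {
      i <- which(ppe$category == parts[[2]] & ppe$variant == parts[[3]])
      if (length(i) != 1) bad_path()
    } else {
      bad_path()
    }
    ppe[[field]][i] <- value
    return(cost_config(wage = config$wage, timing = config$timing, ppe = ppe,
                       equipment = config$equipment, scenarios = config$scenarios,
                       options = config$options))
  }
  bad_path()
}
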