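#' PPE catalogue: one row per item variant
#'
#' The catalogue is a tibble with one row per purchasable variant, grouped
#' into categories. Three costing modes cover the ways PPE is consumed:
#'
#' * `"mixed_variants"` — a category stocked as a mix of interchangeable
#'   variants (e.g. vinyl and nitrile gloves); the per-use cost is the
#'   usage-rate-weighted mean of variant unit costs, rounded to cents.
#'   Usage rates within a category must sum to 1.
#' * `"reusable"` — an item reused a fixed number of times (face shields);
#'   per-use cost is unit cost over `uses_per_unit`, rounded to cents.
#' * `"simple"` — single-use at its unit cost (gowns).
#'
#' The default catalogue holds the post-pandemic prices used in the 2020
#' CVM analysis: gloves at a 50/50 vinyl ($0.06) / nitrile ($0.10) mix,
#' masks at a 30/70 3-ply ($0.75) / N95 ($5.75) mix, $5.00 gowns, and
#' $4.50 face shields amortized over 10 uses — $9.78 per full PPE change.
#'
#' @return A tibble with columns `category`, `mode`, `variant`,
#'   `usage_rate`, `unit_cost` (dollars), `uses_per_unit`.
#' @examples
#' default_ppe_catalogue()
#' kit_cost_per_change(default_ppe_catalogue())  # 9.78
#' @export
default_ppe_catalogue <- function() {
  tibble::tribble(
    ~category,     ~mode,            ~variant,  ~usage_rate, ~unit_cost, ~uses_per_unit,
    "gloves",      "mixed_variants", "vinyl",   0.50,        0.06,       NA_real_,
    "gloves",      "mixed_variants", "nitrile", 0.50,        0.10,       NA_real_,
    "masks",       "mixed_variants", "3-ply",   0.30,        0.75,       NA_real_,
    "masks",       "mixed_variants", "N95",     0.70,        5.75,       NA_real_,
    "gown",        "simple",         NA,        NA_real_,    5.00,       NA_real_,
    "face_shield", "reusable",       NA,        NA_real_,    4.50,       10
  )
}

ppe_modes <- c("mixed_variants", "reusable", "simple")

validate_ppe_catalogue <- function(ppe) {
  required <- c("category", "mode", "variant", "usage_rate", "unit_cost", "uses_per_unit")
  missing <- setdiff(required, names(ppe))
  if (length(missing)) {
    abort_invalid(paste0("PPE catalogue is missing columns: ",
                         paste(missing, collapse = ", ")), field = "ppe")
  }
  if (nrow(ppe) == 0) return(invisible(ppe))
  bad_mode <- setdiff(unique(ppe$mode), ppe_modes)
  if (length(bad_mode)) {
    abort_invalid(paste0("unknown PPE mode(s): ", paste(bad_mode, collapse = ", ")),
                  field = "ppe$mode")
  }
  split_rows <- split(seq_len(nrow(ppe)), factor(ppe$category, unique(ppe$category)))
  for (cat_name in names(split_rows)) {
    rows <- ppe[split_rows[[cat_name]], ]
    mode <- unique(rows$mode)
    if (length(mode) != 1) {
      abort_invalid(sprintf("category '%s' mixes costing modes", cat_name), field = "ppe")
    }
    if (any(is.na(rows$unit_cost)) || any(rows$unit_cost < 0)) {
      abort_invalid(sprintf("category '%s': unit_cost must be >= 0", cat_name),
                    field = "ppe$unit_cost")
    }
    if (mode == "mixed_variants") {
      if (any(is.na(rows$usage_rate)) || any(rows$usage_rate < 0) || any(rows$usage_rate > 1)) {
        abort_invalid(sprintf("category '%s': usage_rate must lie in [0, 1]", cat_name),
                      field = "ppe$usage_rate")
      }
      if (abs(sum(rows$usage_rate) - 1) > 1e-9) {
        abort_invalid(sprintf("category '%s': usage rates sum to %g, not 1",
                              cat_name, sum(rows$usage_rate)),
                      field = "ppe$usage_rate")
      }
    } else {
      if (nrow(rows) != 1) {
        abort_invalid(sprintf("category '%s' (%s) must have exactly one row", cat_name, mode),
                      field = "ppe")
      }
      if (mode == "reusable") {
        upu <- rows$uses_per_unit
        if (is.na(upu) || upu < 1 || upu != trunc(upu)) {
          abort_invalid(sprintf("category '%s': uses_per_unit must be an integer >= 1", cat_name),
                        field = "ppe$uses_per_unit")
        }
      }
    }
  }
  invisible(ppe)
}

category_cost_cents <- function(ppe) {
  validate_ppe_catalogue(ppe)
  idx <- split(seq_len(nrow(ppe)), factor(ppe$category, unique(ppe$category)))
  purrr::map_dbl(idx, function(i) {
    rows <- ppe[i, ]
    switch(rows$mode[[1]],
      mixed_variants = round_half_up(sum(rows$usage_rate * cents(rows$unit_cost))),
      reusable = round_half_up(cents(rows$unit_cost) / rows$uses_per_unit),
      simple = cents(rows$unit_cost)
    )
  })
}

#' Per-use cost of each PPE category
#'
#' Applies each category's costing mode (usage-rate-weighted mean,
#' per-use amortization, or unit cost) and rounds to cents.
#'
#' @param ppe A PPE catalogue tibble (see [default_ppe_catalogue()]).
#' @return A tibble with one row per category: `category`, `mode`,
#'   `cost_per_use` in dollars.
#' @examples
#' ppe_cost_per_use(default_ppe_catalogue())
#' @export
ppe_cost_per_use <- function(ppe) {
  cc <- category_cost_cents(ppe)
  first <- !duplicated(ppe$category)
  tibble::tibble(
    category = ppe$category[first],
    mode = ppe$mode[first],
    cost_per_use = dollars(unname(cc))
  )
}

kit_cost_cents <- function(ppe) {
  sum(category_cost_cents(ppe))
}

#' Cost of one full PPE change
#'
#' The sum of per-use category costs across the catalogue — the material
#' cost avoided each time an in-room visit (and hence a PPE change) is
#' averted. Exact in cents; $9.78 for the default catalogue.
#'
#' @inheritParams ppe_cost_per_use
#' @return Dollars per PPE change.
#' @examples
#' kit_cost_per_change(default_ppe_catalogue())  # 9.78
#' @export
kit_cost_per_change <- function(ppe) {
  dollars(kit_cost_cents(ppe))
}
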