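# Metal concentration bookkeeping: bioaccumulation factors, survival
# rates, and group/day summaries.

#' Bioaccumulation factor
#'
#' Tissue metal concentration (mg/kg dry weight) divided by soil metal
#' concentration (mg/kg). Vectorized.
#'
#' @param worm_conc earthworm concentration(s), mg/kg dry weight, >= 0.
#' @param soil_conc soil concentration(s), mg/kg, > 0.
#' @return the BAF(s), dimensionless.
#' @export
#' @examples
#' round(compute_baf(66.24, 248.67), 3)
compute_baf <- function(worm_conc, soil_conc) {
  if (any(!is.finite(worm_conc)) || any(!is.finite(soil_conc))) {
    stop("concentrations must be finite")
  }
  if (any(soil_conc <= 0)) stop("soil concentration must be positive")
  if (any(worm_conc < 0)) stop("worm concentration must be non-negative")
  worm_conc / soil_conc
}

#' BAF table from exposure records
#'
#' Computes the per-row BAF and a per-metal min/max summary, and flags
#' rows against the conventional screening bounds used in reports
#' (Pb BAF < 0.3, Cd BAF > 10).
#'
#' @param records data frame with columns `group`, `soil`, `metal`, `day`,
#'   `worm_conc`, `soil_conc` (one row per group x soil x day mean).
#' @return a `baf_table`: `rows` (records + `baf`, rounded to 3 decimals in
#'   `baf_3dp`, plus bound flags) and `summary` (per metal: min, max).
#' @export
baf_table <- function(records) {
  need <- c("group", "soil", "metal", "day", "worm_conc", "soil_conc")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) < 1L) stop("need at least one exposure record")
  key <- paste(records$group, records$soil, records$day)
  if (anyDuplicated(key)) {
    stop("duplicate (group, soil, day) record: ", key[duplicated(key)][1])
  }
  rows <- records
  rows$baf <- compute_baf(records$worm_conc, records$soil_conc)
  rows$baf_3dp <- round(rows$baf, 3)
  rows$flag <- ifelse(rows$metal == "Pb" & rows$baf >= 0.3, "Pb BAF >= 0.3",
                      ifelse(rows$metal == "Cd" & rows$baf <= 10,
                             "Cd BAF <= 10", ""))
  summ <- do.call(rbind, lapply(split(rows, rows$metal), function(d) {
    data.frame(metal = d$metal[1], min_baf = min(d$baf), max_baf = max(d$baf))
  }))
  rownames(summ) <- NULL
  structure(list(rows = rows, summary = summ), class = "baf_table")
}

#' @export
print.baf_table <- function(x, ...) {
  cat("<baf_table> ", nrow(x$rows), " records\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: BAF %.3f - %.3f\n", x$summary$metal[i],
                x$summary$min_baf[i], x$summary$max_baf[i]))
  }
  invisible(x)
}

#' Survival rate over an exposure period
#'
#' @param n_initial initial number of worms (> 0).
#' @param n_deaths deaths during the whole period (0 <= deaths <= initial).
#' @return survival rate in `[0, 1]`: `1 - n_deaths / n_initial`.
#' @export
#' @examples
#' survival_rate(30, 1)
survival_rate <- function(n_initial, n_deaths) {
  if (any(n_initial <= 0)) stop("n_initial must be positive")
  if (any(n_deaths < 0) || any(n_deaths > n_initial)) {
    stop("n_deaths must lie between 0 and n_initial")
  }
  1 - n_deaths / n_initial
}

#' Published group-mean metal exposure records
#'
#' The earthworm and soil Pb/Cd concentration means (mg/kg; worms on a dry
#' weight basis) for each treated group, soil and sampling day of the
#' Pb/Cd soil exposure study the package's analyses target, as shipped in
#' `inst/extdata/metal_exposure_means.csv`. These feed [baf_table()] for
#' the bioaccumulation-factor summaries.
#'
#' @return data frame with columns `group`, `soil`, `metal`, `day`,
#'   `worm_conc`, `soil_conc`.
#' @export
metal_exposure_means <- function() {
  utils::read.csv(system.file("extdata", "metal_exposure_means.csv",
                              package = "wormetab", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
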