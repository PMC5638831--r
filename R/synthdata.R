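# Synthetic 1H NMR study generator: class-structured spectra with known
# ground truth, emulating polar tissue extracts measured at 500 MHz.

# Curated peak definitions. Chemical shifts are textbook values for common
# polar-extract metabolites; multiplets are (center_ppm, n_lines,
# j_split_ppm, relative_area). Centers deliberately avoid the water
# exclusion band [4.70, 5.25] ppm so that simulated signal survives
# preprocessing.
.curated_metabolites <- function() {
  m <- function(name, mult, lw = 0.002) {
    md <- do.call(rbind, lapply(mult, function(v) {
      data.frame(center_ppm = v[1], n_lines = as.integer(v[2]),
                 j_split_ppm = v[3], relative_area = v[4])
    }))
    list(name = name, multiplets = md, linewidth_ppm = lw)
  }
  list(
    m("leucine",       list(c(0.96, 2, 0.012, 1.0), c(1.71, 2, 0.014, 0.5), c(3.73, 2, 0.012, 0.3))),
    m("isoleucine",    list(c(0.94, 2, 0.014, 1.0), c(1.01, 2, 0.014, 0.9), c(3.67, 2, 0.008, 0.3))),
    m("valine",        list(c(0.99, 2, 0.014, 1.0), c(1.04, 2, 0.014, 1.0), c(3.61, 2, 0.009, 0.3))),
    m("lactate",       list(c(1.33, 2, 0.014, 3.0), c(4.11, 4, 0.014, 1.0))),
    m("alanine",       list(c(1.48, 2, 0.015, 3.0), c(3.78, 4, 0.015, 1.0))),
    m("acetate",       list(c(1.92, 1, 0, 3.0))),
    m("glutamate",     list(c(2.08, 2, 0.015, 1.0), c(2.35, 2, 0.016, 1.0), c(3.75, 2, 0.010, 0.5))),
    m("succinate",     list(c(2.41, 1, 0, 4.0))),
    m("malate",        list(c(2.37, 2, 0.018, 1.0), c(2.67, 2, 0.018, 1.0), c(4.30, 2, 0.012, 1.0))),
    m("dimethylamine", list(c(2.72, 1, 0, 6.0))),
    m("dimethylglycine", list(c(2.93, 1, 0, 6.0))),
    m("lysine",        list(c(1.72, 2, 0.014, 2.0), c(3.03, 2, 0.014, 2.0))),
    m("choline",       list(c(3.20, 1, 0, 9.0), c(4.07, 2, 0.010, 2.0))),
    m("glycerophosphocholine", list(c(3.23, 1, 0, 9.0), c(3.68, 2, 0.012, 2.0))),
    m("betaine",       list(c(3.26, 1, 0, 9.0), c(3.90, 1, 0, 2.0))),
    m("myo-inositol",  list(c(3.28, 2, 0.018, 1.0), c(3.54, 2, 0.019, 2.0), c(4.06, 2, 0.006, 1.0))),
    m("glycine",       list(c(3.56, 1, 0, 2.0))),
    m("glucose",       list(c(3.42, 2, 0.018, 2.0), c(3.72, 2, 0.016, 2.0), c(4.64, 2, 0.016, 1.0))),
    m("maltose",       list(c(3.60, 2, 0.018, 2.0), c(5.41, 2, 0.008, 1.0))),
    m("uridine",       list(c(5.90, 2, 0.016, 1.0), c(7.87, 2, 0.016, 1.0))),
    m("fumarate",      list(c(6.52, 1, 0, 2.0))),
    m("tyrosine",      list(c(6.89, 2, 0.017, 2.0), c(7.19, 2, 0.017, 2.0))),
    m("histidine",     list(c(7.09, 1, 0, 1.0), c(7.91, 1, 0, 1.0))),
    m("phenylalanine", list(c(7.32, 2, 0.015, 2.0), c(7.42, 3, 0.015, 3.0))),
    m("niacinamide",   list(c(7.59, 2, 0.016, 1.0), c(8.25, 2, 0.016, 1.0), c(8.71, 1, 0, 1.0))),
    m("formate",       list(c(8.46, 1, 0, 1.0))),
    m("inosine",       list(c(6.10, 2, 0.012, 1.0), c(8.23, 1, 0, 1.0), c(8.34, 1, 0, 1.0))),
    m("atp",           list(c(6.14, 2, 0.012, 1.0), c(8.26, 1, 0, 1.0), c(8.52, 1, 0, 1.0))),
    m("amp",           list(c(6.15, 2, 0.012, 1.0), c(8.27, 1, 0, 1.0), c(8.60, 1, 0, 1.0))),
    m("nad",           list(c(8.83, 2, 0.014, 1.0), c(9.14, 1, 0, 1.0), c(9.33, 1, 0, 1.0)))
  )
}

#' Deterministic library of synthetic metabolite peak definitions
#'
#' Returns `n_metabolites` peak definitions for the spectrum simulator. The
#' first entries are curated common polar-extract metabolites (amino acids,
#' TCA intermediates, osmolytes, nucleotides) at textbook chemical shifts;
#' beyond the curated set, filler singlets are placed deterministically on
#' the accessible shift range. All peak centers avoid the water exclusion
#' band (4.70-5.25 ppm) and lie within 0.2-9.5 ppm, and several metabolites
#' carry two or more multiplets at well-separated shifts, which is what
#' STOCSY exploits.
#'
#' @param n_metabolites number of definitions to return (1-60).
#' @return a list of peak definitions; each has `name`, `multiplets`
#'   (data frame with columns `center_ppm`, `n_lines`, `j_split_ppm`,
#'   `relative_area`) and `linewidth_ppm` (full width at half maximum).
#' @export
#' @examples
#' lib <- default_library(10)
#' lib[[4]]$multiplets
default_library <- function(n_metabolites) {
  if (!is.numeric(n_metabolites) || length(n_metabolites) != 1L ||
      n_metabolites < 1 || n_metabolites > 60 || n_metabolites %% 1 != 0) {
    stop("n_metabolites must be a single integer between 1 and 60, got: ",
         format(n_metabolites))
  }
  lib <- .curated_metabolites()
  if (n_metabolites > length(lib)) {
    for (i in (length(lib) + 1L):n_metabolites) {
      center <- 0.25 + ((i * 37) %% 170) / 20  # deterministic grid in [0.25, 8.7]
      if (center > 4.65 && center < 5.30) center <- center + 0.70
      lib[[i]] <- list(
        name = sprintf("synthetic_met_%02d", i),
        multiplets = data.frame(center_ppm = center, n_lines = 1L,
                                j_split_ppm = 0, relative_area = 1.5),
        linewidth_ppm = 0.002
      )
    }
  }
  lib <- lib[seq_len(n_metabolites)]
  centers <- unlist(lapply(lib, function(x) x$multiplets$center_ppm))
  stopifnot(all(centers >= 0.2 & centers <= 9.5),
            !any(centers >= 4.70 & centers <= 5.25))
  lib
}

#' Define a synthetic exposure study
#'
#' Captures the experimental design the spectrum simulator realises: group
#' sizes, per-group multiplicative effects on chosen metabolites, and the
#' magnitude of each nuisance process. The first group is the control and
#' must have fold 1 for every metabolite.
#'
#' @param groups named integer vector of per-group sample counts (first
#'   element is the control group); every count must be >= 2.
#' @param effects named list: metabolite name -> named numeric vector of
#'   fold changes per group label (groups omitted default to fold 1).
#' @param conc_sd_log standard deviation of log concentration within group
#'   (log-normal biological variation).
#' @param dilution_sd_log standard deviation of log per-sample global
#'   dilution factor.
#' @param shift_jitter_sd_ppm per-sample, per-metabolite chemical-shift
#'   jitter (ppm); multiplet internal structure is preserved.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param baseline_offset_sd per-sample constant baseline offset sd.
#' @param seed master seed; named substreams are derived from it.
#' @param ppm_range simulated axis limits (ppm).
#' @param n_points number of grid points.
#' @return a `study_design` object.
#' @export
study_design <- function(groups, effects = list(),
                         conc_sd_log = 0.15, dilution_sd_log = 0.1,
                         shift_jitter_sd_ppm = 0.001, noise_sd = 0.5,
                         baseline_offset_sd = 0.2, seed = 1L,
                         ppm_range = c(0, 10), n_points = 2^14) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named vector of sample counts")
  }
  if (any(groups < 2)) stop("every group needs n_samples >= 2")
  stopifnot(conc_sd_log >= 0, dilution_sd_log >= 0, shift_jitter_sd_ppm >= 0,
            noise_sd >= 0, baseline_offset_sd >= 0,
            length(ppm_range) == 2L, ppm_range[1] < ppm_range[2])
  control <- names(groups)[1]
  for (met in names(effects)) {
    eff <- effects[[met]]
    if (any(eff <= 0)) stop("fold changes must be positive (metabolite ", met, ")")
    if (!is.null(names(eff)) && control %in% names(eff) &&
        eff[[control]] != 1) {
      stop("the control group ('", control, "') must have fold 1.0 for every ",
           "metabolite; violated for ", met)
    }
    unknown <- setdiff(names(eff), names(groups))
    if (length(unknown)) {
      stop("effects for ", met, " reference unknown group(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(groups = groups, effects = effects,
                 conc_sd_log = conc_sd_log, dilution_sd_log = dilution_sd_log,
                 shift_jitter_sd_ppm = shift_jitter_sd_ppm,
                 noise_sd = noise_sd, baseline_offset_sd = baseline_offset_sd,
                 seed = as.integer(seed), ppm_range = ppm_range,
                 n_points = as.integer(n_points)),
            class = "study_design")
}

# Flatten a peak library into one row per Lorentzian line.
.line_table <- function(library) {
  rows <- lapply(seq_along(library), function(j) {
    met <- library[[j]]
    do.call(rbind, lapply(seq_len(nrow(met$multiplets)), function(i) {
      mu <- met$multiplets[i, ]
      offs <- (seq_len(mu$n_lines) - (mu$n_lines + 1) / 2) * mu$j_split_ppm
      data.frame(met = j, pos = mu$center_ppm + offs,
                 area = mu$relative_area / mu$n_lines,
                 gamma = met$linewidth_ppm / 2)
    }))
  })
  do.call(rbind, rows)
}

#' Simulate a class-structured synthetic NMR study
#'
#' Draws per-sample metabolite concentrations (log-normal around
#' base x group fold), global dilution factors, chemical-shift jitter,
#' baseline offsets and additive noise, then renders each sample as a sum
#' of unit-area Lorentzian lines on a shared ppm grid:
#' intensity = dilution x sum over metabolites of conc x sum of lines
#' + baseline + noise. Fully reproducible from `design$seed` via named
#' random substreams.
#'
#' @param library peak definitions from [default_library()] (or compatible).
#' @param design a [study_design()].
#' @return a list with `spectra` (a `spectra_set`) and `truth` (a
#'   `ground_truth`: drawn concentration matrix, dilutions, affected
#'   metabolite names).
#' @export
#' @examples
#' lib <- default_library(5)
#' des <- study_design(c(CON = 3, EXP = 3),
#'                     effects = list(lactate = c(EXP = 2)), seed = 7)
#' sim <- simulate_study(lib, des)
#' dim(sim$spectra$X)
simulate_study <- function(library, design) {
  stopifnot(inherits(design, "study_design"))
  met_names <- vapply(library, `[[`, "", "name")
  if (anyDuplicated(met_names)) stop("library metabolite names must be unique")
  unknown <- setdiff(names(design$effects), met_names)
  if (length(unknown)) {
    stop("effects reference metabolite(s) absent from the library: ",
         paste(unknown, collapse = ", "))
  }

  groups <- design$groups
  n <- sum(groups)
  glabels <- rep(names(groups), groups)
  sample_id <- sprintf("%s_%02d", glabels,
                       unlist(lapply(groups, seq_len), use.names = FALSE))
  p <- length(library)

  # fold matrix: sample x metabolite
  fold <- matrix(1, n, p, dimnames = list(sample_id, met_names))
  for (met in names(design$effects)) {
    eff <- design$effects[[met]]
    for (g in names(eff)) fold[glabels == g, met] <- eff[[g]]
  }

  set.seed(substream_seed(design$seed, "concentrations"))
  conc <- fold * exp(matrix(stats::rnorm(n * p, 0, design$conc_sd_log), n, p))
  dimnames(conc) <- list(sample_id, met_names)
  set.seed(substream_seed(design$seed, "dilutions"))
  dil <- exp(stats::rnorm(n, 0, design$dilution_sd_log))
  names(dil) <- sample_id
  set.seed(substream_seed(design$seed, "jitter"))
  jit <- matrix(stats::rnorm(n * p, 0, design$shift_jitter_sd_ppm), n, p)
  set.seed(substream_seed(design$seed, "baseline"))
  base_off <- stats::rnorm(n, 0, design$baseline_offset_sd)
  set.seed(substream_seed(design$seed, "noise"))
  noise <- matrix(stats::rnorm(n * design$n_points, 0, design$noise_sd),
                  n, design$n_points)

  ppm <- seq(design$ppm_range[1], design$ppm_range[2],
             length.out = design$n_points)
  lines <- .line_table(library)
  X <- matrix(0, n, design$n_points,
              dimnames = list(sample_id, NULL))
  for (i in seq_len(n)) {
    y <- numeric(design$n_points)
    pos <- lines$pos + jit[i, lines$met]
    amp <- conc[i, lines$met] * lines$area
    for (l in seq_len(nrow(lines))) {
      y <- y + amp[l] * stats::dcauchy(ppm, pos[l], lines$gamma[l])
    }
    X[i, ] <- dil[i] * y + base_off[i] + noise[i, ]
  }

  manifest <- data.frame(sample_id = sample_id, group = glabels,
                         stringsAsFactors = FALSE)
  spectra <- structure(list(ppm = ppm, X = X, manifest = manifest,
                            excluded_regions = list()),
                       class = "spectra_set")
  affected <- names(Filter(function(e) any(e != 1), design$effects))
  truth <- structure(list(concentrations = conc, dilutions = dil,
                          affected_metabolites = affected, design = design),
                     class = "ground_truth")
  list(spectra = spectra, truth = truth)
}

#' Write a simulated study to disk as plain-text files
#'
#' One two-column ASCII file (ppm, intensity; descending ppm, the plotting
#' convention) per sample, a `manifest.csv` (sample_id, group, file), and
#' ground-truth CSVs (concentrations, dilutions).
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set <- sim$spectra
  ord <- order(set$ppm, decreasing = TRUE)
  files <- sprintf("%s.txt", set$manifest$sample_id)
  for (i in seq_len(nrow(set$X))) {
    utils::write.table(
      data.frame(ppm = set$ppm[ord], intensity = set$X[i, ord]),
      file.path(dir, files[i]),
      row.names = FALSE, col.names = FALSE, sep = " ")
  }
  manifest <- cbind(set$manifest, file = files)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = rownames(sim$truth$concentrations),
               sim$truth$concentrations, check.names = FALSE),
    file.path(dir, "true_concentrations.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = names(sim$truth$dilutions),
               dilution = sim$truth$dilutions),
    file.path(dir, "true_dilutions.csv"), row.names = FALSE)
  invisible(mpath)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$X), " spectra x ", length(x$ppm),
      " points, ppm ", format(min(x$ppm)), "-", format(max(x$ppm)), "\n",
      sep = "")
  if (length(x$excluded_regions)) {
    cat("  excluded:",
        paste(vapply(x$excluded_regions,
                     function(r) sprintf("[%.2f, %.2f]", r[1], r[2]), ""),
              collapse = ", "), "\n")
  }
  cat("  groups:", paste(sprintf("%s (n=%d)",
                                 names(table(x$manifest$group)),
                                 table(x$manifest$group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Derive metabolite assignment windows from a peak library
#'
#' Builds the assignment table (metabolite, lo_ppm, hi_ppm; one row per
#' multiplet) that bridges bins to metabolite-level integrals, padding each
#' multiplet's line span by `pad` ppm to absorb shift jitter and line
#' width.
#'
#' @param library peak definitions from [default_library()].
#' @param pad half-width padding around each multiplet (ppm).
#' @return data frame with columns `metabolite`, `lo_ppm`, `hi_ppm`.
#' @export
library_assignments <- function(library, pad = 0.01) {
  do.call(rbind, lapply(library, function(met) {
    mu <- met$multiplets
    span <- (mu$n_lines - 1) / 2 * mu$j_split_ppm
    data.frame(metabolite = met$name,
               lo_ppm = mu$center_ppm - span - pad,
               hi_ppm = mu$center_ppm + span + pad)
  }))
}

#' Bin indices dominated by given metabolites
#'
#' Attributes every bin to the library metabolites via the exact integral
#' of each unit-concentration Lorentzian line over the bin interval
#' (Lorentzian tails are heavy, so peak shoulders several bin widths away
#' still belong to their parent resonance). A bin counts as "affected" when
#' the named metabolites contribute at least `min_fraction` of its total
#' library signal and that signal is non-negligible. Used to score how
#' well loading rankings recover planted effects.
#'
#' @param bins data frame with `lo`, `hi` columns (from a `bin_table`).
#' @param library peak definitions.
#' @param metabolites metabolite names.
#' @param min_fraction dominance threshold on the signal fraction.
#' @param min_signal absolute floor, as a fraction of the largest per-bin
#'   library signal, below which a bin is considered empty.
#' @return integer vector of bin indices.
#' @export
affected_bins <- function(bins, library, metabolites, min_fraction = 0.5,
                          min_signal = 1e-3) {
  met_names <- vapply(library, `[[`, "", "name")
  stopifnot(all(metabolites %in% met_names))
  lt <- .line_table(library)
  gam <- lt$gamma
  # exact Lorentzian mass of each line inside each bin
  contrib <- matrix(0, nrow(bins), length(library))
  for (l in seq_len(nrow(lt))) {
    mass <- (atan((bins$hi - lt$pos[l]) / gam[l]) -
             atan((bins$lo - lt$pos[l]) / gam[l])) / pi
    contrib[, lt$met[l]] <- contrib[, lt$met[l]] + lt$area[l] * mass
  }
  tot <- rowSums(contrib)
  aff <- rowSums(contrib[, met_names %in% metabolites, drop = FALSE])
  which(tot > min_signal * max(tot) & aff / tot >= min_fraction)
}
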