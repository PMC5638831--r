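# End-to-end orchestration from a single config: simulate (or read) ->
# preprocess -> model -> STOCSY -> univariate -> pathway -> BAF, with a
# log, config snapshot and output hash manifest.

.known_config_keys <- c("seed", "simulate", "inputs", "preprocess", "model",
                        "comparisons", "stocsy", "pathway", "baf")

#' Validate a pipeline configuration
#'
#' @param config a list or the path of a YAML file.
#' @return the validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys are: ", paste(.known_config_keys, collapse = ", "))
  }
  if (is.null(config$simulate) && is.null(config$inputs$manifest)) {
    stop("config needs either a `simulate:` block or `inputs: manifest:`")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  pp <- config$preprocess %||% list()
  pp$exclude <- pp$exclude %||% list(c(4.70, 5.25))
  pp$range <- unlist(pp$range %||% c(0.2, 8.8))
  pp$target_width <- pp$target_width %||% 0.015
  pp$pqn_reference <- pp$pqn_reference %||% "median"
  config$preprocess <- pp
  md <- config$model %||% list()
  md$ncomp <- md$ncomp %||% 2L
  md$n_osc <- md$n_osc %||% 1L
  md$cv_repeats <- md$cv_repeats %||% 50L
  md$perm_repeats <- md$perm_repeats %||% 7L
  md$n_perm <- md$n_perm %||% 2000L
  config$model <- md
  config
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage in the analysis order: simulate or read
#' spectra, exclude the water region, adaptively bin, PQN-normalize,
#' mean-center, fit and validate one OSC-PLS-DA model per treated-vs-control
#' comparison, run STOCSY for configured drivers, build fold-change tables,
#' run pathway analysis on the significant metabolites, and compute BAF
#' summaries from exposure records. Every artifact is written as CSV/JSON
#' under `out_dir` together with `run.log`, a config snapshot and an MD5
#' hash manifest; identical config + seed gives identical outputs.
#'
#' On a stage failure the partial outputs are moved under `out_dir/failed/`
#' and the error names the stage.
#'
#' @param config list or YAML path; see [validate_config()].
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    cat(format(Sys.time(), "%H:%M:%OS2"), "|", sprintf(...), "\n",
        file = logf, append = TRUE)
  }
  res <- list()
  stage <- function(name, expr) {
    say("stage %s: start", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      fdir <- file.path(out_dir, "failed")
      dir.create(fdir, showWarnings = FALSE)
      arts <- setdiff(list.files(out_dir, full.names = TRUE),
                      c(fdir, logf))
      file.copy(arts, fdir, recursive = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage %s: done in %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  yaml::write_yaml(config, file.path(out_dir, "config_snapshot.yaml"))

  sim_lib <- NULL
  set <- stage("input", {
    if (!is.null(config$simulate)) {
      sb <- config$simulate
      sim_lib <- default_library(sb$n_metabolites %||% 20L)
      groups <- unlist(sb$groups)
      effects <- lapply(sb$effects %||% list(), unlist)
      des <- study_design(
        groups, effects,
        conc_sd_log = sb$conc_sd_log %||% 0.15,
        dilution_sd_log = sb$dilution_sd_log %||% 0.1,
        shift_jitter_sd_ppm = sb$shift_jitter_sd_ppm %||% 0.001,
        noise_sd = sb$noise_sd %||% 0.5,
        baseline_offset_sd = sb$baseline_offset_sd %||% 0.2,
        seed = substream_seed(config$seed, "simulate"))
      sim <- simulate_study(sim_lib, des)
      if (isTRUE(sb$write_spectra)) {
        write_study(sim, file.path(out_dir, "simulated"))
      }
      res$truth <- sim$truth
      sim$spectra
    } else {
      read_spectra(config$inputs$manifest)
    }
  })

  fm <- stage("preprocess", {
    set <- correct_baseline(set)
    for (r in config$preprocess$exclude) set <- exclude_region(set, r[1], r[2])
    bt <- adaptive_bin(set, config$preprocess$range[1],
                       config$preprocess$range[2],
                       config$preprocess$target_width)
    say("binned into %d bins (mean width %.4f ppm)", nrow(bt$bins),
        mean(bt$bins$hi - bt$bins$lo))
    fm <- pqn_normalize(bt, config$preprocess$pqn_reference)
    write_feature_csv(fm, file.path(out_dir, "feature_matrix.csv"))
    fm
  })
  res$feature_matrix <- fm

  comparisons <- config$comparisons %||% list()
  res$models <- stage("model", {
    out <- list()
    for (cmp in comparisons) {
      cmp <- unlist(cmp)
      tag <- paste0(cmp[1], "_vs_", cmp[2])
      sel <- fm$manifest$group %in% cmp
      X <- fm$X[sel, , drop = FALSE]
      y <- fm$manifest$group[sel]
      md <- config$model
      Xc <- center_cols(X)$X
      Xf <- if (md$n_osc > 0) {
        suppressWarnings(osc_filter(Xc, y, md$n_osc))$X
      } else Xc
      fit <- plsda_fit(Xf, y, md$ncomp)
      mv <- permutation_test(X, y, ncomp = md$ncomp, n_perm = md$n_perm,
                             seed = substream_seed(config$seed, tag),
                             n_osc = md$n_osc, cv_repeats = md$perm_repeats,
                             full_repeats = md$cv_repeats)
      dir.create(file.path(out_dir, paste0("model_", tag)),
                 showWarnings = FALSE)
      mdir <- file.path(out_dir, paste0("model_", tag))
      utils::write.csv(data.frame(sample_id = fm$manifest$sample_id[sel],
                                  group = y, fit$scores),
                       file.path(mdir, "scores.csv"), row.names = FALSE)
      utils::write.csv(data.frame(ppm = fm$ppm, weights = fit$x_weights,
                                  loadings = fit$x_loadings),
                       file.path(mdir, "loadings.csv"), row.names = FALSE)
      sp <- splot(fit, X)
      utils::write.csv(sp, file.path(mdir, "splot.csv"), row.names = FALSE)
      fmc <- fm; fmc$X <- X; fmc$manifest <- fm$manifest[sel, ]
      cl <- correlation_loadings(fit, fmc)
      utils::write.csv(cl, file.path(mdir, "correlation_loadings.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(r2y = mv$r2y, q2y = mv$q2y, p_perm = mv$p_perm,
             n_perm = mv$n_perm, r2x_removed_osc = if (md$n_osc > 0)
               suppressWarnings(osc_filter(Xc, y, md$n_osc))$filter$r2x_removed
             else 0),
        file.path(mdir, "validation.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(null_q2y = mv$null_stats),
                       file.path(mdir, "null_stats.csv"), row.names = FALSE)
      say("model %s: R2Y=%.3f Q2Y=%.3f p=%.4g", tag, mv$r2y, mv$q2y, mv$p_perm)
      out[[tag]] <- list(fit = fit, validation = mv)
    }
    out
  })

  if (!is.null(config$stocsy)) {
    stage("stocsy", {
      for (d in unlist(config$stocsy$drivers)) {
        st <- stocsy_1d(fm, d)
        utils::write.csv(st$profile,
                         file.path(out_dir, sprintf("stocsy_%0.2f.csv", d)),
                         row.names = FALSE)
      }
    })
  }

  res$fold_changes <- stage("univariate", {
    assignments <- if (!is.null(config$inputs$assignments)) {
      utils::read.csv(config$inputs$assignments, stringsAsFactors = FALSE)
    } else if (!is.null(sim_lib)) {
      library_assignments(sim_lib)
    } else NULL
    if (is.null(assignments) || !length(comparisons)) return(NULL)
    # keep only windows that intersect the binned range
    hit <- vapply(seq_len(nrow(assignments)), function(i) {
      any(fm$ppm >= assignments$lo_ppm[i] & fm$ppm <= assignments$hi_ppm[i])
    }, logical(1))
    dropped <- setdiff(assignments$metabolite,
                       assignments$metabolite[hit])
    if (length(dropped)) {
      say("univariate: dropping metabolite(s) outside the binned range: %s",
          paste(dropped, collapse = ", "))
    }
    assignments <- assignments[hit, , drop = FALSE]
    ints <- metabolite_integrals(fm, assignments)
    tab <- build_fold_change_table(ints, fm$manifest, comparisons)
    write_fold_change_table(tab, file.path(out_dir, "fold_changes.csv"),
                            file.path(out_dir, "fold_changes.html"))
    tab
  })

  if (!is.null(config$pathway) || !is.null(res$fold_changes)) {
    res$pathways <- stage("pathway", {
      lib <- if (!is.null(config$pathway$index)) {
        read_pathway_library(config$pathway$index)
      } else toy_pathway_library()
      hits <- if (!is.null(res$fold_changes)) {
        unique(res$fold_changes$metabolite[res$fold_changes$q_bh < 0.05])
      } else character(0)
      universe <- unique(c(unlist(lapply(lib, `[[`, "nodes")), hits))
      pr <- metpa(hits, lib, universe)
      utils::write.csv(as.data.frame(pr),
                       file.path(out_dir, "pathway_results.csv"),
                       row.names = FALSE)
      pr
    })
  }

  if (!is.null(config$inputs$exposure) || isTRUE(config$baf)) {
    res$baf <- stage("baf", {
      rec <- if (!is.null(config$inputs$exposure)) {
        utils::read.csv(config$inputs$exposure, stringsAsFactors = FALSE)
      } else metal_exposure_means()
      bt <- baf_table(rec)
      utils::write.csv(bt$rows, file.path(out_dir, "baf.csv"),
                       row.names = FALSE)
      utils::write.csv(bt$summary, file.path(out_dir, "baf_summary.csv"),
                       row.names = FALSE)
      bt
    })
  }

  stage("hashes", {
    arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE,
                       pattern = "\\.(csv|json|yaml)$")
    h <- tools::md5sum(arts)
    utils::write.csv(
      data.frame(file = sub(paste0("^", out_dir, "/?"), "", names(h)),
                 md5 = unname(h)),
      file.path(out_dir, "hash_manifest.csv"), row.names = FALSE)
  })
  say("pipeline complete")
  invisible(res)
}
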