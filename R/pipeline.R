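#' Read/write a flat experiment configuration
#'
#' A minimal `key = value` text format (comments with `#`); values are
#' parsed as numeric vectors when possible (comma-separated), otherwise
#' kept as strings. Every stochastic stage derives a child seed from the
#' single `seed` entry via [child_seed()], so a config round-trips to a
#' byte-identical experiment.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    out[[p[1]]] <- if (!anyNA(num)) num else trimws(v)
  }
  out
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE,
                                       trim = TRUE), collapse = ",")),
    character(1)), path)
  invisible(path)
}

#' Run the parental-relatedness classifier experiment
#'
#' End-to-end: simulates `n_train + n_test` offspring per union class on a
#' synthetic genome (truth autozygosity tracts, no caller noise), extracts
#' the 15 ROH statistics, trains `n_trials` classifiers on independent
#' resamples of `n_train` per class, applies majority voting to a held-out
#' evaluation set of `n_test` per class, and reports 10-class and 3-class
#' accuracies with the confusion matrix.
#'
#' @param n_train,n_test training pool and held-out evaluation individuals
#'   per class (defaults 500 pool / trial draws of 400, and 100).
#' @param n_train_per_class training examples per class per trial.
#' @param n_trials voting trials (default 10).
#' @param classes union classes simulated.
#' @param map synthetic genome map.
#' @param seed master seed.
#' @param hyper classifier hyper-parameters (see [train_classifier()]).
#' @return list with `accuracy10`, `accuracy3`, `confusion`, `voted`,
#'   `truth`, `r_hat` (rates from the voted counts via
#'   [estimate_r_from_counts()]), `k_hat`, and the experiment parameters.
#' @export
run_classifier_experiment <- function(n_train = 500, n_test = 100,
                                      n_train_per_class = 400, n_trials = 10,
                                      classes = union_classes,
                                      map = uniform_genome_map(), seed = 1,
                                      hyper = list()) {
  if (n_test == 0 || n_train == 0) {
    return(list(accuracy10 = NA_real_, accuracy3 = NA_real_,
                confusion = NULL, voted = character(), truth = character(),
                r_hat = NULL, k_hat = NA_real_, seed = seed,
                n_train = n_train, n_test = n_test, n_trials = n_trials))
  }
  if (n_train < n_train_per_class)
    stop("training pool smaller than per-trial draw")
  message(sprintf("[classifier] simulating %d+%d offspring x %d classes (seed %d)",
                  n_train, n_test, length(classes), seed))
  pool <- simulate_union_cohort(classes, n = n_train, map = map,
                                seed = child_seed(seed, "train_pool"))
  eval_set <- simulate_union_cohort(classes, n = n_test, map = map,
                                    seed = child_seed(seed, "eval_set"))
  X_pool <- t(vapply(pool$tract_cM, extract_features, numeric(15)))
  X_eval <- t(vapply(eval_set$tract_cM, extract_features, numeric(15)))
  message("[classifier] training ", n_trials, " trial models")
  models <- lapply(seq_len(n_trials), function(b)
    train_classifier(X_pool, pool$class, n_train_per_class, hyper = hyper,
                     seed = child_seed(seed, paste0("trial", b))))
  voted <- predict_with_voting(models, X_eval)
  truth <- eval_set$class
  acc10 <- evaluate_accuracy(voted, truth)
  acc3 <- evaluate_accuracy(voted, truth, three_class_map)
  counts <- table(factor(voted, levels = classes))
  r_hat <- estimate_r_from_counts(as.numeric(counts) |>
                                    stats::setNames(classes))
  k_hat <- tryCatch(kinship_from_r(r_hat), error = function(e) NA_real_)
  list(accuracy10 = acc10, accuracy3 = acc3,
       confusion = table(truth = truth, voted = voted),
       voted = voted, truth = truth, r_hat = r_hat, k_hat = k_hat,
       seed = seed, n_train = n_train, n_test = n_test, n_trials = n_trials)
}

#' Run the footprint model for a parameter set
#'
#' Computes expected ROH and IBD footprint curves for an Ne trajectory and
#' consanguinity rates; optionally also empirical curves from supplied
#' segment tables on the same bins.
#'
#' @param eff an [effective_trajectory()] (from [rescale_ne()] for
#'   estimator output, or [effective_trajectory()] for model parameters).
#' @param r consanguinity rates (r1..r5).
#' @param chrom_cM chromosome lengths in cM.
#' @param lmin,lmax,binsize footprint bins (cM).
#' @param T_switch,mc_iterations,seed within-distribution controls, see
#'   [tmrca_within()].
#' @param k_historic optional historic kinship for t > T_switch (the
#'   sudden-change experiment); the tail then uses an effective trajectory
#'   recomputed at this kinship from the same pair counts.
#' @param roh_segments,ibd_segments optional observed [segment_table()]s.
#' @param n_individuals sample size behind the observed tables.
#' @return list with `expected_roh`, `expected_ibd`, and (when segments
#'   are given) `observed_roh`, `observed_ibd`.
#' @export
run_footprint_experiment <- function(eff, r, chrom_cM, lmin = 5, lmax = 30,
                                     binsize = 1, T_switch = 50,
                                     mc_iterations = 1e5, seed = 1,
                                     k_historic = NULL,
                                     roh_segments = NULL, ibd_segments = NULL,
                                     n_individuals = NULL) {
  eff_tail <- eff
  if (!is.null(k_historic)) {
    # same pair counts, historic kinship: S = 4 Ne (1 - 3 k_hist)
    ne_pairs <- eff$S / (4 * (1 - 3 * eff$k))
    eff_tail <- effective_trajectory(ne_pairs, k_historic,
                                     horizon = length(eff$S))
  }
  dist_b <- tmrca_between(eff)
  dist_w <- tmrca_within(eff, r, T_switch = T_switch,
                         mc_iterations = mc_iterations,
                         seed = child_seed(seed, "within"),
                         eff_tail = eff_tail)
  out <- list(
    expected_roh = expected_footprint(dist_w, chrom_cM, lmin, lmax, binsize),
    expected_ibd = expected_footprint(dist_b, chrom_cM, lmin, lmax, binsize))
  if (!is.null(roh_segments)) {
    if (is.null(n_individuals)) stop("n_individuals required with observed segments")
    out$observed_roh <- empirical_footprint(roh_segments, n_individuals,
                                            sum(chrom_cM), lmin, lmax,
                                            binsize, mode = "roh")
  }
  if (!is.null(ibd_segments)) {
    if (is.null(n_individuals)) stop("n_individuals required with observed segments")
    out$observed_ibd <- empirical_footprint(ibd_segments, n_individuals,
                                            sum(chrom_cM), lmin, lmax,
                                            binsize, mode = "ibd")
  }
  out
}

#' Command-line entry point
#'
#' A small dispatcher mirroring the package's main operations, intended to
#' be called from an Rscript wrapper (see `inst/cli/consang-kit`):
#' \preformatted{
#' consang-kit kinship --r 0,0.235,0.052,0.155,0
#' consang-kit estimate-r --counts sibling=2,first_cousin_g1=10 --n 100
#' consang-kit footprint-expected --ne-file ne.tsv --r ... --out curve.tsv
#' consang-kit validate --segments file.tsv
#' consang-kit run classifier --config cfg.txt --out dir
#' }
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
consang_kit_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    args[i[1] + 1]
  }
  cmd <- if (length(args)) args[1] else "help"
  status <- 0L
  if (cmd == "kinship") {
    r <- as.numeric(strsplit(getopt("--r", "0"), ",")[[1]])
    cat(sprintf("k = %.6f\n", kinship_from_r(r)))
  } else if (cmd == "estimate-r") {
    kvs <- strsplit(strsplit(getopt("--counts", ""), ",")[[1]], "=")
    counts <- stats::setNames(as.numeric(vapply(kvs, `[`, "", 2)),
                              vapply(kvs, `[`, "", 1))
    n <- as.numeric(getopt("--n", sum(counts)))
    r <- estimate_r_from_counts(counts, n)
    cat(sprintf("r%d = %.7f\n", 1:5, r), sep = "")
  } else if (cmd == "validate") {
    tab <- read_segment_table(getopt("--segments"))
    cat(sprintf("OK: %d segments (%d ROH, %d IBD)\n", nrow(tab),
                sum(is_roh(tab)), sum(!is_roh(tab))))
  } else if (cmd == "footprint-expected") {
    traj <- read_ne_trajectory(getopt("--ne-file"))
    r <- as.numeric(strsplit(getopt("--r", "0"), ",")[[1]])
    k <- kinship_from_r(r)
    eff <- rescale_ne(traj, k)
    map <- uniform_genome_map()
    res <- run_footprint_experiment(
      eff, r, map_lengths(map)$cM,
      lmin = as.numeric(getopt("--lmin", "5")),
      lmax = as.numeric(getopt("--lmax", "30")),
      seed = as.integer(getopt("--seed", "1")))
    mode <- getopt("--mode", "roh")
    write_footprint(if (mode == "roh") res$expected_roh else res$expected_ibd,
                    getopt("--out", paste0("footprint_", mode, ".tsv")))
  } else if (cmd == "run") {
    what <- args[2]
    cfg <- read_config(getopt("--config"))
    out_dir <- getopt("--out", ".")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(getopt("--seed", cfg$seed %||% 1))
    if (identical(what, "classifier")) {
      n_train <- cfg$n_train %||% 500
      res <- run_classifier_experiment(
        n_train = n_train, n_test = cfg$n_test %||% 100,
        n_train_per_class = cfg$n_train_per_class %||%
          min(400, max(1, round(0.8 * n_train))),
        n_trials = cfg$n_trials %||% 10, seed = seed)
      utils::write.table(
        data.frame(metric = c("accuracy10", "accuracy3"),
                   value = c(res$accuracy10, res$accuracy3)),
        file.path(out_dir, "classifier_report.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(seed = seed, n_train = res$n_train,
                                n_test = res$n_test, n_trials = res$n_trials,
                                accuracy10 = res$accuracy10,
                                accuracy3 = res$accuracy3),
                           file.path(out_dir, "classifier_report.json"),
                           auto_unbox = TRUE, digits = NA)
    } else stop("unknown run target: ", what)
  } else {
    cat("usage: consang-kit <kinship|estimate-r|validate|footprint-expected|run> [options]\n")
    status <- if (cmd == "help") 0L else 1L
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
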