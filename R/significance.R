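#' Monte-Carlo empirical p-value for a module's HMS
#'
#' Samples `N` random gene subsets of the same size from the background
#' universe, rebuilds each sample's hierarchy with the same builder and
#' configuration as the observed module, scores it, and reports the
#' empirical p-value `(r + 1) / (N + 1)`, where `r` is the number of null
#' samples scoring at least the observed HMS. The `+1` correction keeps the
#' p-value strictly positive.
#'
#' Two null builders are available. `"tafi"` rebuilds a fresh hierarchy per
#' sample from the bag of genes — the mode matching a module that was itself
#' reconstructed. `"fixed_tree"` keeps the observed tree's topology and
#' permutes sampled genes onto its leaves — the mode for modules whose
#' hierarchy was given as input.
#'
#' @param genes character vector: the module's genes (ignored when `tree`
#'   is supplied, whose leaves define the module).
#' @param background character vector: the gene universe to sample from.
#' @param annotations named list mapping gene IDs to term-ID vectors.
#' @param tax a [taxonomy].
#' @param config a [scoring_config].
#' @param N number of Monte-Carlo samples.
#' @param seed integer seed for reproducibility.
#' @param builder `"tafi"` or `"fixed_tree"`.
#' @param tree a [module_tree] (required for `builder = "fixed_tree"`).
#' @param alpha,beta TAFI parameters (used by the `"tafi"` builder).
#' @param unannotated policy for unannotated genes (see [annotate_module]);
#'   defaults to `"root"` so arbitrary background draws always score.
#' @return an object of class `"hms_test"`: observed `hms`, `p_value`,
#'   `n_samples`, `n_exceed`, `seed` and the vector of null scores.
#' @export
monte_carlo_pvalue <- function(genes = NULL, background, annotations, tax,
                               config = scoring_config(), N = 1000,
                               seed = NULL,
                               builder = c("tafi", "fixed_tree"),
                               tree = NULL, alpha = 0.9, beta = 0.1,
                               unannotated = "root") {
  builder <- match.arg(builder)
  if (builder == "fixed_tree") {
    if (is.null(tree)) stop("builder = \"fixed_tree\" needs a tree")
    genes <- unique(unname(tree$genes))
  }
  genes <- unique(genes)
  if (length(genes) < 2L) stop("module must contain at least 2 genes")
  if (N < 1L) stop("N must be >= 1")
  background <- unique(background)
  if (length(background) < length(genes)) {
    stop("background smaller than the module")
  }
  if (!all(genes %in% background)) {
    warning("module genes not all contained in the background universe")
  }

  score_bag <- function(bag) {
    if (builder == "tafi") {
      fit <- tafi(bag, annotations, tax, alpha = alpha, beta = beta,
                  config = config, unannotated = unannotated)
      hms(fit$forest, tax, config)
    } else {
      t2 <- tree
      t2$genes <- setNames(bag, names(tree$genes))
      am <- annotate_module(t2, annotations, tax, unannotated = unannotated)
      hms(am, tax, config)
    }
  }

  observed <- if (builder == "fixed_tree") {
    hms(annotate_module(tree, annotations, tax, unannotated = unannotated),
        tax, config)
  } else {
    score_bag(genes)
  }

  if (!is.null(seed)) set.seed(seed)
  null_scores <- vapply(seq_len(N), function(i) {
    score_bag(sample(background, length(genes)))
  }, numeric(1))
  r <- sum(null_scores >= observed - 1e-12)
  structure(list(hms = observed, p_value = (r + 1) / (N + 1),
                 n_samples = N, n_exceed = r, seed = seed,
                 null_scores = null_scores, builder = builder),
            class = "hms_test")
}

#' @export
print.hms_test <- function(x, ...) {
  cat("Monte-Carlo test of hierarchical modularity\n")
  cat(sprintf("  HMS = %.4f   p = %.4g   (r = %d of N = %d null samples >= observed)\n",
              x$hms, x$p_value, x$n_exceed, x$n_samples))
  cat(sprintf("  null builder: %s   seed: %s\n", x$builder,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Calibrate the penalization parameter theta against a validation set
#'
#' Scans a grid of theta values and returns the largest one for which at
#' least `coverage_target` of the validation modules are significant at
#' `alpha_level` by the Monte-Carlo test. If no grid value reaches the
#' target, the theta maximizing coverage is returned with a warning.
#'
#' @param validation_modules list of character vectors (gene sets known to
#'   be functionally coherent, e.g. curated complexes).
#' @param background,annotations,tax,N,seed,builder,alpha,beta,unannotated
#'   passed to [monte_carlo_pvalue].
#' @param theta_grid positive theta values, ascending.
#' @param alpha_level significance threshold on the empirical p-value.
#' @param coverage_target fraction of validation modules required to be
#'   significant.
#' @param config base [scoring_config]; its theta is replaced by each grid
#'   value in turn.
#' @return list with `theta` (the chosen value) and `coverage` (named
#'   fraction per grid value).
#' @export
calibrate_theta <- function(validation_modules, background, annotations, tax,
                            theta_grid, alpha_level = 0.05,
                            coverage_target = 0.9, N = 1000, seed = NULL,
                            config = scoring_config(),
                            builder = "tafi", alpha = 0.9, beta = 0.1,
                            unannotated = "root") {
  if (length(validation_modules) == 0L) stop("empty validation set")
  if (any(theta_grid <= 0)) stop("theta_grid must be positive")
  if (is.unsorted(theta_grid)) stop("theta_grid must be ascending")
  if (!(coverage_target > 0 && coverage_target <= 1)) {
    stop("coverage_target must be in (0, 1]")
  }
  coverage <- vapply(theta_grid, function(th) {
    cfg <- config; cfg$theta <- th
    sig <- vapply(seq_along(validation_modules), function(i) {
      rep_seed <- if (is.null(seed)) NULL else seed + i
      monte_carlo_pvalue(validation_modules[[i]], background, annotations,
                         tax, cfg, N = N, seed = rep_seed, builder = builder,
                         alpha = alpha, beta = beta,
                         unannotated = unannotated)$p_value <= alpha_level
    }, logical(1))
    mean(sig)
  }, numeric(1))
  names(coverage) <- theta_grid
  ok <- which(coverage >= coverage_target)
  if (length(ok)) {
    theta <- theta_grid[max(ok)]
  } else {
    warning("no theta reaches the coverage target; returning the coverage-maximizing value")
    theta <- theta_grid[which.max(coverage)]
  }
  list(theta = theta, coverage = coverage)
}
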