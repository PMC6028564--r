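#' Specify a synthetic two-group connectome cohort
#'
#' Defines the study conditions for a simulated case/control cohort of ROI
#' time series. Both groups share a common baseline inter-regional
#' correlation `base_rho`; in the case group the correlation of each planted
#' region pair is shifted to `base_rho + delta_rho`. Defaults mirror a
#' typical resting-state cohort on the 90-region AAL parcellation with 110
#' retained time points.
#'
#' @param n_per_group Subjects per class (positive integer).
#' @param n_regions Number of brain regions R (default 90).
#' @param n_timepoints Time points T per subject (default 110).
#' @param planted_pairs List of length-2 integer vectors (1-based region
#'   indices) whose correlation differs between groups.
#' @param delta_rho Correlation shift magnitude in `[0, 1)`.
#' @param base_rho Baseline inter-region correlation.
#' @param noise_sd Marginal standard deviation (signal amplitude) of each
#'   region's series; rescaling leaves the correlation structure untouched.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, n_regions = 90, n_timepoints = 110,
                        planted_pairs = list(), delta_rho = 0,
                        base_rho = 0.1, noise_sd = 1, seed = 1L) {
  if (!is_count(n_per_group)) stop_ctx("n_per_group must be a positive integer")
  if (!is_count(n_regions) || n_regions < 2) stop_ctx("n_regions must be >= 2")
  if (!is_count(n_timepoints) || n_timepoints < 3)
    stop_ctx("n_timepoints must be >= 3 (correlation undefined below)")
  if (delta_rho < 0 || delta_rho >= 1) stop_ctx("delta_rho must be in [0, 1)")
  if (noise_sd <= 0) stop_ctx("noise_sd must be positive")
  planted_pairs <- lapply(planted_pairs, function(p) sort(as.integer(p)))
  for (p in planted_pairs) {
    if (length(p) != 2 || p[1] == p[2] || any(p < 1) || any(p > n_regions))
      stop_ctx("planted pair (%s) is not a distinct pair of region indices in 1..%d",
               paste(p, collapse = ","), n_regions)
  }
  keys <- vapply(planted_pairs, paste, "", collapse = "-")
  if (anyDuplicated(keys)) stop_ctx("planted pairs must be distinct")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 planted_pairs = planted_pairs,
                 delta_rho = delta_rho, base_rho = base_rho,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Population correlation matrix for one group: base_rho everywhere
# off-diagonal, planted pairs overwritten for the case group.
target_correlation <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  R <- spec$n_regions
  S <- matrix(spec$base_rho, R, R)
  diag(S) <- 1
  if (group == "case") {
    for (p in spec$planted_pairs) {
      S[p[1], p[2]] <- S[p[2], p[1]] <- spec$base_rho + spec$delta_rho
    }
  }
  S
}

check_psd <- function(S, spec, group, repair = FALSE, tol = 1e-10) {
  ev <- eigen(S, symmetric = TRUE, only.values = !repair)
  if (min(ev$values) >= -tol) return(S)
  if (!repair) {
    pairs <- vapply(spec$planted_pairs, function(p)
      sprintf("(%d,%d)", p[1], p[2]), "")
    stop_ctx(paste0("target correlation matrix for the %s group is not ",
                    "positive semi-definite (min eigenvalue %.3g); the ",
                    "planted pairs %s are jointly inconsistent with ",
                    "base_rho = %g, delta_rho = %g"),
             group, min(ev$values),
             paste(pairs, collapse = " "), spec$base_rho, spec$delta_rho)
  }
  lam <- pmax(ev$values, tol)
  S2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  d <- sqrt(diag(S2))
  S2 / tcrossprod(d)
}

#' Generate a synthetic cohort of ROI time series
#'
#' Draws each subject's T-by-R time-series matrix from a multivariate normal
#' distribution with the group's target correlation matrix (see
#' [cohort_spec()]). Control subjects get the baseline correlation structure;
#' case subjects additionally carry the planted correlation shifts.
#'
#' @param spec A [cohort_spec()].
#' @param repair If `TRUE`, a non-positive-semi-definite target matrix is
#'   repaired by eigenvalue clipping instead of raising an error.
#' @return A list of `2 * n_per_group` subject records, each a list with
#'   `subject_id`, `label` (factor, levels `control`/`case`) and `timeseries`
#'   (T-by-R matrix). Controls come first.
#' @export
generate_cohort <- function(spec, repair = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  Sg <- list(control = check_psd(target_correlation(spec, "control"),
                                 spec, "control", repair),
             case = check_psd(target_correlation(spec, "case"),
                              spec, "case", repair))
  with_seed(spec$seed, {
    subjects <- vector("list", 2L * spec$n_per_group)
    idx <- 0L
    for (grp in c("control", "case")) {
      Sigma <- spec$noise_sd^2 * Sg[[grp]]
      for (i in seq_len(spec$n_per_group)) {
        idx <- idx + 1L
        ts <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, spec$n_regions),
                            Sigma = Sigma)
        colnames(ts) <- sprintf("R%03d", seq_len(spec$n_regions))
        subjects[[idx]] <- list(
          subject_id = sprintf("%s_%03d", grp, i),
          label = factor(grp, levels = c("control", "case")),
          timeseries = ts)
      }
    }
    subjects
  })
}

#' Generate a labelled feature table with planted group differences
#'
#' Fast path for testing the ensemble machinery without time series: features
#' are unit-variance Gaussian; planted features carry a between-class mean
#' difference of `effect_size` (standardised, split +/- effect_size/2 around
#' zero), all others have no class difference.
#'
#' @param n_per_group Subjects per class.
#' @param p Number of features.
#' @param planted_features Integer indices (1-based) of discriminative features.
#' @param effect_size Standardised between-class mean shift (>= 0).
#' @param seed Integer RNG seed.
#' @return A [feature_table()] with `labels` attached (controls first).
#' @export
generate_feature_table <- function(n_per_group, p, planted_features = integer(0),
                                   effect_size = 0, seed = 1L) {
  if (!is_count(n_per_group)) stop_ctx("n_per_group must be a positive integer")
  if (!is_count(p)) stop_ctx("p must be a positive integer")
  planted_features <- as.integer(planted_features)
  if (length(planted_features) &&
      (any(planted_features < 1) || any(planted_features > p)))
    stop_ctx("planted feature indices must lie in 1..%d", p)
  if (effect_size < 0) stop_ctx("effect_size must be >= 0")
  n <- 2L * n_per_group
  with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    labels <- factor(rep(c("control", "case"), each = n_per_group),
                     levels = c("control", "case"))
    shift <- effect_size / 2
    x[labels == "control", planted_features] <-
      x[labels == "control", planted_features] - shift
    x[labels == "case", planted_features] <-
      x[labels == "case", planted_features] + shift
    colnames(x) <- sprintf("f%04d", seq_len(p))
    feature_table(x, labels,
                  subject_ids = sprintf("%s_%03d", labels,
                                        c(seq_len(n_per_group),
                                          seq_len(n_per_group))))
  })
}

#' Recall and precision of a recovered feature set
#'
#' @param selected Integer indices of selected features.
#' @param planted Integer indices of truly discriminative features.
#' @return A list with `recall` = |selected n planted| / |planted| and
#'   `precision` = |selected n planted| / |selected| (0 for an empty
#'   selection).
#' @export
planted_recovery <- function(selected, planted) {
  selected <- unique(as.integer(selected))
  planted <- unique(as.integer(planted))
  hit <- length(intersect(selected, planted))
  list(recall = if (length(planted)) hit / length(planted) else NA_real_,
       precision = if (length(selected)) hit / length(selected) else 0)
}
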