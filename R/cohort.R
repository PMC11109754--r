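# Synthetic cohort generation, calibrated to the published cohort
# summary statistics (60 male subjects x 5 single-leg landing trials).
#
# Subject-level summary variables are drawn from a multivariate normal
# distribution (the source cohort passed Kolmogorov-Smirnov normality
# checks) whose means/SDs and AICA-/AROM-row correlations are the
# published values.  Pairs not published are filled by a two-factor
# model with AICA and AROM as the common factors, which reproduces every
# anchored correlation exactly and is positive semidefinite by
# construction whenever the implied communalities stay below 1.

.table1_variables <- c("AICA", "AROM", "PVGRF", "TED", "PADM", "PKFM",
                       "PHFM", "PAIA", "PAIM", "PAF")

#' Calibrated cohort summary statistics
#'
#' The default calibration of the synthetic cohort generator: means and
#' standard deviations of the ten summary variables, their correlations
#' with the two ankle motion pattern anchors (AICA, AROM), and the
#' cross-risk correlation target r(PAF, PAIA) = -0.330 used to pin the
#' anchor correlation.
#'
#' @return A list with `variables`, `means`, `sds`, `cor_aica`,
#'   `cor_arom`, `cross_pair`, `cross_target`.
#' @export
cohort_calibration <- function() {
  list(
    variables = .table1_variables,
    means = c(AICA = 33.47, AROM = 59.99, PVGRF = 36.61, TED = 6.01,
              PADM = 1.61, PKFM = 3.13, PHFM = 1.58, PAIA = 14.19,
              PAIM = 0.75, PAF = 14.72),
    sds = c(AICA = 5.16, AROM = 8.35, PVGRF = 5.10, TED = 0.77,
            PADM = 0.32, PKFM = 0.56, PHFM = 0.40, PAIA = 2.74,
            PAIM = 0.23, PAF = 1.68),
    cor_aica = c(PVGRF = -0.591, TED = 0.490, PADM = -0.542, PKFM = -0.441,
                 PHFM = -0.253, PAIA = 0.502, PAIM = -0.268, PAF = -0.554),
    cor_arom = c(PVGRF = -0.451, TED = 0.687, PADM = -0.357, PKFM = -0.284,
                 PHFM = -0.357, PAIA = 0.600, PAIM = -0.138, PAF = -0.332),
    cross_pair = c("PAF", "PAIA"),
    cross_target = -0.330
  )
}

# Solve the AICA-AROM anchor correlation c so that the two-factor fill
# reproduces a target correlation for one named cross pair:
#   r_ij(c) = (vi.vj - c (vi1 vj2 + vi2 vj1)) / (1 - c^2)  = target
# which is a quadratic in c; the root inside (-1, 1) is returned.
.solve_anchor_cor <- function(vi, vj, target) {
  s1 <- sum(vi * vj)
  sx <- vi[1] * vj[2] + vi[2] * vj[1]
  roots <- polyroot(c(s1 - target, -sx, target))
  roots <- Re(roots[abs(Im(roots)) < 1e-8])
  roots <- roots[abs(roots) < 1]
  if (length(roots) == 0L) {
    stop("no admissible anchor correlation reproduces the cross-risk target",
         call. = FALSE)
  }
  roots[which.min(abs(roots))]
}

#' Build the cohort correlation matrix
#'
#' Assembles the full correlation matrix of the summary variables from
#' the anchored AICA-/AROM-row correlations.  Non-anchored pairs are
#' filled by a two-factor (product-of-paths) model with AICA and AROM as
#' common factors; the AICA-AROM correlation itself is solved so that
#' the implied correlation of `cross_pair` equals `cross_target`
#' (default: r(PAF, PAIA) = -0.330).  The result is projected to the
#' nearest valid correlation matrix when numerically required; the
#' Frobenius distance moved is recorded in the
#' `"projection_distance"` attribute.
#'
#' @param calibration A list shaped like [cohort_calibration()].
#' @param anchor_cor Optional explicit AICA-AROM correlation; when
#'   `NULL` it is solved from the cross-risk target.
#' @return Correlation matrix with attributes `anchor_cor` and
#'   `projection_distance`.
#' @export
build_correlation_matrix <- function(calibration = cohort_calibration(),
                                     anchor_cor = NULL) {
  vars <- calibration$variables
  others <- setdiff(vars, c("AICA", "AROM"))
  ra <- calibration$cor_aica[others]
  rr <- calibration$cor_arom[others]
  if (any(is.na(ra)) || any(is.na(rr))) {
    stop("calibration must anchor every non-AICA/AROM variable", call. = FALSE)
  }
  if (is.null(anchor_cor)) {
    cp <- calibration$cross_pair
    anchor_cor <- .solve_anchor_cor(
      c(calibration$cor_aica[cp[1]], calibration$cor_arom[cp[1]]),
      c(calibration$cor_aica[cp[2]], calibration$cor_arom[cp[2]]),
      calibration$cross_target
    )
  }
  if (abs(anchor_cor) >= 1) stop("anchor correlation must lie in (-1, 1)", call. = FALSE)
  R2 <- matrix(c(1, anchor_cor, anchor_cor, 1), 2)
  R2inv <- solve(R2)
  p <- length(vars)
  P <- diag(p)
  dimnames(P) <- list(vars, vars)
  P["AICA", "AROM"] <- P["AROM", "AICA"] <- anchor_cor
  load <- t(vapply(others, function(v) as.numeric(R2inv %*% c(ra[v], rr[v])),
                   numeric(2)))
  for (v in others) {
    P["AICA", v] <- P[v, "AICA"] <- ra[v]
    P["AROM", v] <- P[v, "AROM"] <- rr[v]
  }
  for (i in seq_along(others)) {
    for (j in seq_along(others)) {
      if (i != j) {
        P[others[i], others[j]] <-
          as.numeric(load[i, , drop = FALSE] %*% R2 %*% load[j, ])
      }
    }
  }
  comm <- rowSums((load %*% R2) * load)
  if (any(comm > 1 + 1e-8)) {
    warning("two-factor fill implies communality > 1; relying on projection")
  }
  dist <- 0
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    proj <- as.matrix(Matrix::nearPD(P, corr = TRUE)$mat)
    dist <- norm(proj - P, "F")
    dimnames(proj) <- dimnames(P)
    P <- proj
  }
  structure(P, anchor_cor = anchor_cor, projection_distance = dist)
}

#' Cohort generator configuration
#'
#' @param n_subjects Number of subjects (default 60).
#' @param trials_per_subject Trials per subject (default 5).
#' @param calibration Summary-statistic calibration, see
#'   [cohort_calibration()].
#' @param cor_matrix Optional pre-built correlation matrix; defaults to
#'   [build_correlation_matrix()] on the calibration.
#' @param noise_fraction Within-subject trial noise SD as a fraction of
#'   the between-subject SD (default 0.2; the source protocol does not
#'   report within-subject variance, so this is a documented free
#'   parameter).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 60L, trials_per_subject = 5L,
                          calibration = cohort_calibration(),
                          cor_matrix = NULL, noise_fraction = 0.2) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2", call. = FALSE)
  if (trials_per_subject < 1L) stop("trials_per_subject must be at least 1", call. = FALSE)
  if (noise_fraction < 0) stop("noise_fraction must be non-negative", call. = FALSE)
  if (any(calibration$sds <= 0)) {
    stop("calibration SDs must all be positive", call. = FALSE)
  }
  if (is.null(cor_matrix)) cor_matrix <- build_correlation_matrix(calibration)
  if (!isSymmetric(unname(as.matrix(cor_matrix))) ||
      any(abs(diag(cor_matrix) - 1) > 1e-8)) {
    stop("cor_matrix must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(cor_matrix, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("cor_matrix must be positive semidefinite", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_subject = as.integer(trials_per_subject),
         calibration = calibration, cor_matrix = cor_matrix,
         noise_fraction = noise_fraction),
    class = "cohort_config"
  )
}

#' Generate a summary-level synthetic cohort
#'
#' Draws subject-level summary vectors from the configured multivariate
#' normal distribution, adds independent within-subject trial noise, and
#' returns both the trial-level table and the subject-mean table (the
#' unit of analysis for the correlation statistics).
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG state
#'   is used (useful for replicate loops under one outer seed).
#' @return An object of class `summary_cohort`: list with `trials`
#'   (data frame: subject, trial, variables), `subjects` (data frame of
#'   within-subject trial means) and `config`.
#' @export
generate_summary_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  cal <- config$calibration
  vars <- cal$variables
  mu <- cal$means[vars]
  sds <- cal$sds[vars]
  Sigma <- diag(sds) %*% config$cor_matrix[vars, vars] %*% diag(sds)
  ns <- config$n_subjects
  nt <- config$trials_per_subject
  latent <- MASS::mvrnorm(ns, mu = mu, Sigma = Sigma)
  colnames(latent) <- vars
  trials <- latent[rep(seq_len(ns), each = nt), , drop = FALSE]
  noise_sd <- config$noise_fraction * sds
  for (j in seq_along(vars)) {
    trials[, j] <- trials[, j] + stats::rnorm(ns * nt, sd = noise_sd[j])
  }
  trials_df <- data.frame(subject = rep(seq_len(ns), each = nt),
                          trial = rep(seq_len(nt), times = ns),
                          trials, row.names = NULL)
  subj_means <- stats::aggregate(trials_df[vars],
                                 by = list(subject = trials_df$subject), mean)
  structure(
    list(trials = trials_df, subjects = subj_means, config = config),
    class = "summary_cohort"
  )
}

#' @export
print.summary_cohort <- function(x, ...) {
  cat(sprintf("<summary_cohort> %d subjects x %d trials, %d variables\n",
              x$config$n_subjects, x$config$trials_per_subject,
              length(x$config$calibration$variables)))
  invisible(x)
}
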