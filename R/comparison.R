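#' Model evidence table
#'
#' Free energies for a set of candidate models across subjects, with model
#' labels (orientation method, location surface, orientation surface) used
#' to group models into families.
#'
#' @param F Subjects x models numeric matrix of free energies.
#' @param model_labels Data frame with one row per model; typically columns
#'   `method`, `location_surface`, `orientation_surface`. Row order matches
#'   the columns of `F`. A `model` column of unique names is added when
#'   absent.
#' @return Object of class `evidence_table`.
#' @export
evidence_table <- function(F, model_labels = NULL) {
  F <- as.matrix(F)
  if (is.null(model_labels)) {
    model_labels <- data.frame(model = colnames(F) %||% paste0("m", seq_len(ncol(F))))
  }
  model_labels <- as.data.frame(model_labels)
  if (nrow(model_labels) != ncol(F)) stop("one label row per model is required")
  if (is.null(model_labels$model)) {
    model_labels$model <- do.call(paste, c(model_labels, sep = "."))
  }
  if (anyDuplicated(model_labels$model)) stop("model names must be unique")
  colnames(F) <- model_labels$model
  structure(list(F = F, model_labels = model_labels,
                 n_subjects = nrow(F), n_models = ncol(F)),
            class = "evidence_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("evidence_table: %d subjects x %d models\n", x$n_subjects, x$n_models))
  invisible(x)
}

#' Free energy differences against a reference model
#'
#' `delta F[s, j] = F[s, j] - F[s, reference]`: the log Bayes factor of model
#' j against the reference, per subject. The reference column is all zeros.
#'
#' @param table An `evidence_table`.
#' @param reference_model Model name (or 1-based column index).
#' @return Subjects x models matrix of delta-F values.
#' @export
delta_f <- function(table, reference_model) {
  stopifnot(inherits(table, "evidence_table"))
  ref <- if (is.character(reference_model)) {
    match(reference_model, colnames(table$F))
  } else as.integer(reference_model)
  if (is.na(ref) || ref < 1 || ref > table$n_models) {
    stop("unknown reference model: ", reference_model)
  }
  table$F - table$F[, ref]
}

#' Classify a free energy difference against the significance threshold
#'
#' A model is "better" than the reference when `delta F` exceeds the
#' threshold (default 3, i.e. a Bayes factor of about exp(3) = 20), "worse"
#' when below the negated threshold, and "indistinguishable" otherwise
#' (strict inequalities). The implied Bayes factor `exp(|delta F|)` is
#' attached.
#'
#' @param delta_f_value Finite numeric (vectorized).
#' @param threshold Significance threshold in nats (default 3).
#' @return Character vector in {"better", "worse", "indistinguishable"} with
#'   attribute `bayes_factor`.
#' @export
significant <- function(delta_f_value, threshold = 3) {
  stopifnot(all(is.finite(delta_f_value)))
  out <- ifelse(delta_f_value > threshold, "better",
                ifelse(delta_f_value < -threshold, "worse", "indistinguishable"))
  attr(out, "bayes_factor") <- exp(abs(delta_f_value))
  out
}

# family-aggregated log evidence: log-sum-exp of member F minus log count
# (uniform within-family model prior)
family_log_evidence <- function(F, families) {
  t(vapply(seq_len(nrow(F)), function(s) {
    vapply(families, function(idx) logsumexp(F[s, idx]) - log(length(idx)), numeric(1))
  }, numeric(length(families))))
}

#' Random-effects family-level Bayesian model comparison
#'
#' Groups models into families, combines the evidence of models within each
#' family (log-sum-exp under a uniform within-family prior), and computes
#' each family's exceedance probability — the posterior belief that this
#' family is more frequent in the population than every other — under the
#' hierarchical Dirichlet-multinomial random-effects model, sampled by Gibbs.
#'
#' @param table An `evidence_table`.
#' @param grouping Either a grouping label ("method", "location",
#'   "orientation", "method-location") resolved against the model labels, or
#'   a named list mapping family name -> model indices/names (must partition
#'   the model set).
#' @param n_samples Posterior draws after burn-in (default 1e5).
#' @param burn_in Burn-in draws (default 1e3).
#' @param alpha0 Dirichlet concentration per family (default 1).
#' @param seed Integer seed.
#' @return List: `exceedance` (named, sums to 1), `expected_r` (posterior
#'   mean family frequencies), `families`.
#' @export
compare_families <- function(table, grouping, n_samples = 1e5, burn_in = 1e3,
                             alpha0 = 1, seed = 1) {
  stopifnot(inherits(table, "evidence_table"))
  families <- resolve_families(table, grouping)
  if (length(families) < 2) stop("at least 2 families are required")
  if (any(lengths(families) == 0)) stop("empty family")
  if (!setequal(unlist(families), seq_len(table$n_models))) {
    stop("families must partition the model set")
  }
  lme <- family_log_evidence(table$F, families)     # subjects x K
  K <- length(families); S <- nrow(lme)
  lme <- lme - apply(lme, 1, max)

  draws <- withr::with_seed(seed, {
    r <- rep(1 / K, K)
    wins <- numeric(K)
    r_sum <- numeric(K)
    u_z <- matrix(runif((n_samples + burn_in) * S), ncol = S)
    for (it in seq_len(n_samples + burn_in)) {
      # z_n | r  ~ Cat over families
      p <- exp(sweep(lme, 2, log(r), `+`))
      p <- p / rowSums(p)
      cum <- p %*% upper.tri(diag(K), diag = TRUE)
      z <- rowSums(u_z[it, ] > cum) + 1L
      # r | z ~ Dirichlet(alpha0 + counts)
      cnt <- tabulate(z, nbins = K)
      g <- rgamma(K, shape = alpha0 + cnt, rate = 1)
      r <- g / sum(g)
      if (it > burn_in) {
        wins[which.max(r)] <- wins[which.max(r)] + 1
        r_sum <- r_sum + r
      }
    }
    list(wins = wins, r_sum = r_sum)
  })
  ep <- draws$wins / n_samples
  names(ep) <- names(families)
  list(exceedance = ep, expected_r = setNames(draws$r_sum / n_samples, names(families)),
       families = families)
}

# Resolve a grouping spec into a named list of model-index vectors.
resolve_families <- function(table, grouping) {
  lbl <- table$model_labels
  if (is.character(grouping) && length(grouping) == 1) {
    key <- switch(grouping,
      method = lbl$method,
      location = lbl$location_surface,
      orientation = lbl$orientation_surface,
      "method-location" = paste(lbl$method, lbl$location_surface, sep = "/"),
      stop("unknown grouping: ", grouping))
    if (is.null(key)) stop("model labels lack the columns needed for grouping '",
                           grouping, "'")
    return(split(seq_len(table$n_models), key))
  }
  lapply(grouping, function(idx) {
    if (is.character(idx)) idx <- match(idx, colnames(table$F))
    if (any(is.na(idx))) stop("unknown model in family definition")
    as.integer(idx)
  })
}

#' Deterministic 2-family exceedance probability by quadrature
#'
#' Independent oracle for the 2-family case: integrates the (non-conjugate)
#' posterior over the first family's frequency r directly,
#' `p(r) \propto r^(a-1) (1-r)^(a-1) prod_n (r B_n1 + (1-r) B_n2)`,
#' and returns `P(r > 1/2)`.
#'
#' @param table An `evidence_table`.
#' @param grouping As in [compare_families()]; must yield exactly 2 families.
#' @param alpha0 Dirichlet concentration (default 1).
#' @return Named length-2 vector of exceedance probabilities.
#' @export
exceedance_2family_quadrature <- function(table, grouping, alpha0 = 1) {
  families <- resolve_families(table, grouping)
  stopifnot(length(families) == 2)
  lme <- family_log_evidence(table$F, families)
  lme <- lme - apply(lme, 1, max)
  B <- exp(lme)
  dens <- function(r) {
    vapply(r, function(ri) {
      exp((alpha0 - 1) * (log(ri) + log(1 - ri)) +
            sum(log(ri * B[, 1] + (1 - ri) * B[, 2])))
    }, numeric(1))
  }
  z <- integrate(dens, 0, 1, rel.tol = 1e-10)$value
  p1 <- integrate(dens, 0.5, 1, rel.tol = 1e-10)$value / z
  setNames(c(p1, 1 - p1), names(families))
}
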