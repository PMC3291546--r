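# Group-comparison layer: a permutation test of dispersion homogeneity on
# centroid distances (the distance-based analogue of a multivariate
# variance decomposition), bootstrap contrasts of niche metrics, and a thin
# adapter over nlme for the mixed-model stage.

#' Permutation test of dispersion homogeneity
#'
#' Tests whether groups differ in their average distance to their own
#' centroid (i.e. in multivariate spread), in the spirit of a
#' permutation-based homogeneity-of-dispersion analysis. The statistic is
#' the one-way ANOVA F on the distances across groups; the null
#' distribution is built by permuting group labels over *individuals*, so
#' all records of an individual move together — this respects the
#' dependence of multiple tissues measured on the same animal. The p-value
#' uses the add-one rule \code{(1 + #permuted >= observed) / (1 + n_perm)}
#' and is therefore never exactly zero.
#'
#' @param distance Numeric vector of non-negative distances.
#' @param group Group label per record (2+ groups, 2+ records each).
#' @param individual Optional permutation-unit label per record; default
#'   treats each record as its own unit. Each individual must lie in
#'   exactly one group.
#' @param n_perm Number of permutations, >= 99. Default 9999.
#' @param seed Optional integer seed; with a fixed seed the result is
#'   byte-identical across runs.
#' @return Object of class \code{dispersion_test}: list with
#'   \code{statistic} ("F"), \code{observed}, \code{p_value},
#'   \code{n_perm}, \code{seed}, \code{groups}, \code{n_records},
#'   \code{n_individuals}.
#' @export
permutation_dispersion_test <- function(distance, group, individual = NULL,
                                        n_perm = 9999, seed = NULL) {
  if (!is.numeric(distance) || any(!is.finite(distance)))
    stop("distances must be finite numeric", call. = FALSE)
  group <- as.character(group)
  if (length(group) != length(distance))
    stop("group and distance lengths differ", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (is.null(individual)) individual <- as.character(seq_along(distance))
  individual <- as.character(individual)

  lev <- sort(unique(group))
  k <- length(lev)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs at least 2 records", call. = FALSE)
  ind_group <- tapply(group, individual, unique)
  if (any(lengths(ind_group) > 1L))
    stop("an individual spans more than one group", call. = FALSE)

  n <- length(distance)
  tot <- sum(distance)
  sst <- sum(distance^2) - tot^2 / n
  if (sst <= 1e-12)
    stop("distances have zero variance; F statistic undefined", call. = FALSE)

  # per-individual sufficient statistics: permuting individuals only needs
  # each one's record count and distance sum
  ind <- sort(unique(individual))
  m <- length(ind)
  c_i <- as.numeric(table(factor(individual, levels = ind)))
  s_i <- as.numeric(tapply(distance, factor(individual, levels = ind), sum))
  g_i <- as.character(ind_group[ind])
  blocks <- lapply(lev, function(l) which(g_i == l))
  sizes <- lengths(blocks)

  f_of <- function(ord) {
    # ord: permutation of 1..m; first sizes[1] individuals -> group 1, etc.
    ssb <- 0
    at <- 0L
    for (j in seq_len(k)) {
      idx <- ord[(at + 1L):(at + sizes[j])]
      at <- at + sizes[j]
      ng <- sum(c_i[idx])
      ssb <- ssb + sum(s_i[idx])^2 / ng
    }
    ssb <- ssb - tot^2 / n
    ssw <- sst - ssb
    (ssb / (k - 1)) / (ssw / (n - k))
  }

  observed <- f_of(unlist(blocks))
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) f_of(sample.int(m)),
                 numeric(1))
  p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_perm)
  structure(list(statistic = "F", observed = observed, p_value = p,
                 n_perm = as.integer(n_perm), seed = seed, groups = lev,
                 n_records = n, n_individuals = m,
                 perm_quantiles = stats::quantile(perm, c(.5, .9, .95, .99))),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Permutation dispersion test (%d groups: %s)\n",
              length(x$groups), paste(x$groups, collapse = ", ")))
  cat(sprintf("  F = %.4f, p = %.4g (%d permutations of %d individuals)\n",
              x$observed, x$p_value, x$n_perm, x$n_individuals))
  invisible(x)
}

metric_value <- function(s, metric, habitat, age, tnw_scope) {
  switch(metric,
         tnw = total_niche_width(s, habitat, age),
         wic = within_individual_component(s, habitat, age),
         wic_tnw = specialization_index(s, habitat, age, tnw_scope)$wic_tnw,
         contrast_breadth = {
           sub <- s[s$habitat == habitat & s$age == age, , drop = FALSE]
           mean(individual_contrasts(sample_set(as.data.frame(sub)))$breadth)
         },
         stop("unknown metric: ", metric, call. = FALSE))
}

resample_group <- function(s, habitat, age) {
  sub <- as.data.frame(s[s$habitat == habitat & s$age == age, , drop = FALSE])
  idx <- split(seq_len(nrow(sub)), sub$individual_id)
  draw <- sample(length(idx), length(idx), replace = TRUE)
  take <- idx[draw]
  out <- sub[unlist(take, use.names = FALSE), , drop = FALSE]
  # drawn copies of one animal become distinct resampled individuals
  out$individual_id <- paste0("bs", rep(seq_along(take), lengths(take)),
                              ".", out$individual_id)
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence interval for a between-group metric contrast
#'
#' Percentile CI for \code{metric(group1) - metric(group2)}, resampling
#' individuals (not samples) with replacement within each group so that an
#' animal's tissues stay together. Replicates on which the metric is not
#' computable (e.g. a resample with no muscle+collagen individual, or zero
#' TNW) are redrawn; the number of redraws is reported.
#'
#' @param s A [sample_set()].
#' @param metric One of \code{"tnw"}, \code{"wic"}, \code{"wic_tnw"},
#'   \code{"contrast_breadth"}.
#' @param group1,group2 Lists with elements \code{habitat} and \code{age}.
#' @param n_boot Bootstrap replicates, >= 100. Default 1999.
#' @param conf Nominal coverage. Default 0.95.
#' @param seed Optional integer seed.
#' @param tnw_scope Passed through for \code{"wic_tnw"}.
#' @return List with \code{estimate}, \code{lower}, \code{upper},
#'   \code{conf}, \code{n_boot}, \code{n_redraws}, \code{seed},
#'   \code{metric}.
#' @export
bootstrap_contrast <- function(s, metric, group1, group2, n_boot = 1999,
                               conf = 0.95, seed = NULL,
                               tnw_scope = "paired") {
  stopifnot(inherits(s, "sample_set"))
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  est1 <- metric_value(s, metric, group1$habitat, group1$age, tnw_scope)
  est2 <- metric_value(s, metric, group2$habitat, group2$age, tnw_scope)
  same <- identical(group1$habitat, group2$habitat) &&
    identical(group1$age, group2$age)
  estimate <- if (same) 0 else est1 - est2
  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    tries <- 0L
    repeat {
      val <- tryCatch({
        r1 <- sample_set(resample_group(s, group1$habitat, group1$age))
        v1 <- metric_value(r1, metric, group1$habitat, group1$age, tnw_scope)
        r2 <- sample_set(resample_group(s, group2$habitat, group2$age))
        v2 <- metric_value(r2, metric, group2$habitat, group2$age, tnw_scope)
        v1 - v2
      }, error = function(e) NA_real_)
      if (is.finite(val)) break
      redraws <- redraws + 1L
      tries <- tries + 1L
      if (tries > 200L)
        stop("bootstrap replicate repeatedly degenerate for metric ", metric,
             call. = FALSE)
    }
    boot[b] <- val
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  list(metric = metric, estimate = estimate, lower = ci[1], upper = ci[2],
       conf = conf, n_boot = as.integer(n_boot), n_redraws = redraws,
       seed = seed)
}

#' Declare a mixed-model analysis
#'
#' A declarative description of one mixed-model stage: the response, the
#' fixed-effect formula, the random intercept terms, and whether residual
#' variance follows a power of the fitted mean. Random terms are only
#' permitted when the data carry replicate structure for them (checked at
#' fit time).
#'
#' @param response Response column name (e.g. \code{"d13c"},
#'   \code{"distance"}, \code{"breadth"}).
#' @param fixed Right-hand-side fixed-effect formula as a string, e.g.
#'   \code{"habitat * age * tissue"}.
#' @param random Character subset of \code{c("province", "individual")};
#'   \code{"individual"} requests tissue-within-individual nesting.
#' @param var_power Model residual sd as a power of the fitted mean.
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(response, fixed = "habitat * age * tissue",
                       random = c("province", "individual"),
                       var_power = TRUE) {
  random <- match.arg(random, several.ok = TRUE)
  structure(list(response = response, fixed = fixed, random = random,
                 var_power = isTRUE(var_power)),
            class = "model_spec")
}

#' Fit the fixed-effect stage of a declared mixed model
#'
#' A validated adapter over \code{nlme::lme}: random intercepts for
#' province and (optionally) individual nested within province stand in for
#' spatial autocorrelation and tissue-within-individual dependence, and
#' \code{nlme::varPower()} on the fitted mean absorbs non-equal variances
#' between factor levels. Denominator degrees of freedom are whatever the
#' engine's containment method yields and are reported verbatim.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing the response and all factors named by
#'   the spec (\code{province}, \code{individual_id} as required).
#' @return Object of class \code{model_summary}: \code{anova} (data frame
#'   \code{effect}, \code{num_df}, \code{den_df}, \code{F}, \code{p}),
#'   \code{varcomp} (named sd estimates), \code{var_power_exponent},
#'   \code{converged}, \code{engine}, \code{message}. On non-convergence
#'   \code{converged} is \code{FALSE} and no F values are reported.
#' @export
fit_group_effects <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  if (!spec$response %in% names(data))
    stop("response column '", spec$response, "' not in data", call. = FALSE)
  vars <- all.vars(stats::reformulate(spec$fixed))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("fixed-effect column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("individual" %in% spec$random) {
    if (!"individual_id" %in% names(data))
      stop("random term 'individual' needs an individual_id column",
           call. = FALSE)
    if (max(table(data$individual_id)) < 2L)
      stop("random term 'individual' requires replicate records per individual",
           call. = FALSE)
  }
  if ("province" %in% spec$random && !"province" %in% names(data))
    stop("random term 'province' needs a province column", call. = FALSE)

  if (stats::var(data[[spec$response]]) == 0)
    return(structure(list(anova = NULL, varcomp = NULL,
                          var_power_exponent = NA_real_, converged = FALSE,
                          engine = "nlme::lme",
                          message = "response is constant; degenerate fit"),
                     class = "model_summary"))
  d <- data
  for (v in vars) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  fixed <- stats::reformulate(spec$fixed, response = spec$response)
  random <- if (all(c("province", "individual") %in% spec$random))
    stats::as.formula("~ 1 | province/individual_id")
  else if ("province" %in% spec$random)
    stats::as.formula("~ 1 | province")
  else
    stats::as.formula("~ 1 | individual_id")
  weights <- if (spec$var_power) nlme::varPower(form = ~ fitted(.)) else NULL

  fit <- tryCatch(
    nlme::lme(fixed = fixed, random = random, weights = weights, data = d,
              method = "REML",
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(anova = NULL, varcomp = NULL,
                          var_power_exponent = NA_real_, converged = FALSE,
                          engine = "nlme::lme",
                          message = conditionMessage(fit)),
                     class = "model_summary"))
  }
  an <- stats::anova(fit)
  an <- an[rownames(an) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(effect = rownames(an), num_df = an$numDF,
                    den_df = an$denDF, F = an[["F-value"]],
                    p = an[["p-value"]], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  names(sds) <- rownames(vc)
  exponent <- if (spec$var_power)
    unname(stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE))
  else NA_real_
  structure(list(anova = tab, varcomp = sds[is.finite(sds)],
                 var_power_exponent = exponent, converged = TRUE,
                 engine = "nlme::lme", message = ""),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  if (!x$converged) {
    cat("Mixed model did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Mixed model (%s), variance power exponent %.3f\n",
              x$engine, x$var_power_exponent))
  print.data.frame(x$anova, digits = 4)
  invisible(x)
}
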