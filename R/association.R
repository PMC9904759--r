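#' Phenotype-covariate association fits
#'
#' Phenotypes are normalized to the mean of the wild-type control group and
#' related to molecular covariates with two bespoke fits: a one-phase
#' exponential decay Y = a*exp(-k*X) + b (protein vs antisense-transcript
#' level) and ordinary linear regression Y = a*X + b with a two-sided test
#' of slope = 0 (normalized phenotype vs protein level).
#'
#' @name association
NULL

#' Normalize values to the wild-type control group mean
#'
#' @param values Numeric phenotype values.
#' @param group Character group labels, same length.
#' @param reference Label of the normalizing group.
#' @return Data frame \code{value}, \code{group}, \code{normalized}; the
#'   reference group's mean normalized value is 1 by construction.
#' @export
normalize_to_wt <- function(values, group, reference = "WT-control") {
  stopifnot(length(values) == length(group))
  ref <- values[group == reference]
  if (length(ref) == 0) stop("reference group '", reference, "' is empty")
  m <- mean(ref)
  if (!is.finite(m) || m <= 0)
    stop("reference group mean must be positive (got ", m, ")")
  data.frame(value = values, group = group, normalized = values / m)
}

#' One-phase exponential decay fit Y = a*exp(-k*X) + b
#'
#' Nonlinear least squares (Levenberg-Marquardt) with k constrained
#' non-negative. Initialization: b0 = min(y), a0 = max(y) - b0, k0 from a
#' log-linearization of y - b0, plus jittered restarts; the best of all
#' converged starts is returned. With k estimated at (numerical) zero the
#' (a, b) split is not identifiable and is flagged.
#'
#' @param x,y Numeric vectors (>= 4 points, x spread > 0).
#' @param n_restarts Number of jittered restarts beyond the deterministic
#'   start.
#' @return List: \code{a}, \code{k}, \code{b}, \code{r_squared},
#'   \code{identifiable} (FALSE when k ~ 0), \code{fit} (the nls object).
#' @export
fit_exp_decay <- function(x, y, n_restarts = 5) {
  if (length(x) < 4) stop("need at least 4 points")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (stats::sd(x) == 0) stop("x has no spread")

  b0 <- min(y)
  a0 <- max(y) - b0
  if (a0 <= 0) a0 <- max(abs(y), 1e-3)
  pos <- y - b0 + 0.05 * a0
  k0 <- tryCatch({
    cf <- stats::lm.fit(cbind(1, x), log(pmax(pos, 1e-12)))$coefficients
    max(1e-3, -cf[2])
  }, error = function(e) 1)

  starts <- list(c(a = a0, k = k0, b = b0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  # jitter stream seeded from an order-invariant digest so fits ignore row order
  set.seed(as.integer(sum(round(abs(y) * 1e4)) %% 1000000))
  for (j in seq_len(n_restarts)) {
    starts[[j + 1]] <- c(a = a0 * stats::runif(1, 0.3, 3),
                         k = k0 * stats::runif(1, 0.2, 5),
                         b = b0 + stats::runif(1, -0.5, 0.5) * max(a0, 1e-3))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-k * x) + b,
                        start = as.list(st),
                        lower = c(a = -Inf, k = 0, b = -Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("exponential-decay fit failed to converge from all ",
         length(starts), " starts")
  cf <- stats::coef(best)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best_rss / sst else NA_real_
  # the (a, b) split is undetermined when the decay term adds nothing over
  # the best constant fit (k ~ 0, a ~ 0, or constant y all land here)
  improves <- (sst - best_rss) > 1e-8 * max(sst, .Machine$double.eps)
  list(a = unname(cf["a"]), k = unname(cf["k"]), b = unname(cf["b"]),
       r_squared = r2,
       identifiable = unname(cf["k"]) > 1e-8 && improves,
       fit = best)
}

#' Linear regression with slope-zero test
#'
#' Ordinary least squares Y = a*X + b; \code{p_slope} is the conventional
#' two-sided t-test of slope = 0.
#'
#' @param x,y Numeric vectors (>= 3 points, x spread > 0).
#' @return List: \code{a} (slope), \code{b} (intercept), \code{r_squared},
#'   \code{p_slope}, \code{n}, \code{fit}.
#' @export
fit_linear <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients[2, 4],
       n = length(x), fit = fit)
}

#' Assemble the per-animal phenotype vs protein-level table
#'
#' Joins the cohort manifest (covariates) with per-animal phenotype values,
#' normalizes each phenotype by the wild-type control group mean, and
#' returns one row per animal with all phenotype columns, ready for
#' \code{\link{fit_linear}} per phenotype.
#'
#' @param manifest Cohort manifest (animal_id, genotype, treatment,
#'   protein_level columns).
#' @param phenotypes Data frame with \code{animal_id} plus one numeric
#'   column per phenotype.
#' @param reference_genotype,reference_treatment Labels identifying the
#'   normalizing group.
#' @return Data frame: animal_id, genotype, treatment, protein_level, and
#'   one normalized column per phenotype.
#' @export
phenotype_protein_table <- function(manifest, phenotypes,
                                    reference_genotype = "WT",
                                    reference_treatment = "control") {
  missing_cov <- setdiff(phenotypes$animal_id, manifest$animal_id)
  if (length(missing_cov) > 0)
    stop("missing covariates for animal ", missing_cov[1])
  missing_ph <- setdiff(manifest$animal_id, phenotypes$animal_id)
  if (length(missing_ph) > 0)
    stop("missing phenotypes for animal ", missing_ph[1])
  df <- merge(manifest[, c("animal_id", "genotype", "treatment", "protein_level")],
              phenotypes, by = "animal_id")
  is_ref <- df$genotype == reference_genotype & df$treatment == reference_treatment
  if (!any(is_ref)) stop("no animals in the reference group")
  for (col in setdiff(names(phenotypes), "animal_id")) {
    m <- mean(df[[col]][is_ref])
    if (!is.finite(m) || m <= 0)
      stop("reference mean for phenotype '", col, "' must be positive")
    df[[col]] <- df[[col]] / m
  }
  df
}
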