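#' Bundle one fluctuation experiment
#'
#' A culture set holds the per-culture selective (e.g. rifampicin) colony
#' counts of one Luria-Delbruck fluctuation assay together with the final
#' population size per culture, `N_t`, estimated from CFU dilution plating.
#'
#' @param counts integer vector of resistant-colony counts, one per parallel
#'   culture; all must be non-negative.
#' @param final_population final viable population per culture (CFU), `N_t`.
#' @param plating_fraction fraction of each culture plated selectively.
#'   The estimators here assume essentially complete plating; a warning is
#'   emitted below 0.9 because no partial-plating correction is applied.
#' @param label free-text label for the experiment.
#' @return An object of class `culture_set`: a list with elements `counts`,
#'   `n_cultures`, `final_population`, `plating_fraction`, `label`.
#' @examples
#' cs <- culture_set(c(0, 0, 1, 5, 0, 112), final_population = 1e8)
#' cs$n_cultures
#' @export
culture_set <- function(counts, final_population,
                        plating_fraction = 249 / 250, label = "") {
  if (length(counts) < 1) stop("at least one culture count is required")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers")
  if (!is.numeric(final_population) || length(final_population) != 1 ||
      is.na(final_population) || final_population <= 0)
    stop("'final_population' (N_t) must be a single positive number")
  if (plating_fraction <= 0 || plating_fraction > 1)
    stop("'plating_fraction' must be in (0, 1]")
  if (plating_fraction < 0.9)
    warning("plating_fraction < 0.9: no partial-plating correction is applied; ",
            "estimates assume the whole culture was plated")
  structure(
    list(counts = as.integer(counts), n_cultures = length(counts),
         final_population = as.numeric(final_population),
         plating_fraction = plating_fraction, label = label),
    class = "culture_set")
}

#' @export
print.culture_set <- function(x, ...) {
  cat("Fluctuation culture set", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  cultures:", x$n_cultures,
      " counts: median", stats::median(x$counts), "max", max(x$counts),
      "\n  N_t:", format(x$final_population, digits = 3), "CFU\n")
  invisible(x)
}

#' Luria-Delbruck mutant-count distribution (Ma-Sandri-Sarkar recursion)
#'
#' Computes the probability mass function of the number of mutant colonies
#' per culture when `m` mutational events per culture are expected, using
#' the Ma-Sandri-Sarkar recursion
#' \deqn{p_0 = e^{-m}, \qquad
#'       p_r = \frac{m}{r} \sum_{i=0}^{r-1} \frac{p_i}{r - i + 1}.}
#' This is the compound-Poisson distribution whose clone sizes follow
#' \eqn{P(S = s) = 1/(s(s+1))}, the classical Luria-Delbruck law for
#' mutants arising during deterministic exponential growth.
#'
#' @param m expected number of mutational events per culture (>= 0).
#' @param rmax truncation index; the pmf is returned for counts `0:rmax`.
#' @return An object of class `ld_dist`: list with `m`, `pmf` (length
#'   `rmax + 1`), `rmax`, and `tail_mass` (probability above `rmax`).
#' @examples
#' d <- ld_pmf(1, 10)
#' d$pmf[1]            # exp(-1)
#' sum(d$pmf) + d$tail_mass
#' @export
ld_pmf <- function(m, rmax) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0)
    stop("'m' must be a single non-negative number")
  if (length(rmax) != 1 || is.na(rmax) || rmax < 0 || rmax != floor(rmax))
    stop("'rmax' must be a single non-negative integer")
  rmax <- as.integer(rmax)
  p <- numeric(rmax + 1)
  p[1] <- exp(-m)
  if (rmax >= 1) {
    for (r in seq_len(rmax)) {
      # p_i for i = 0..r-1 divided by (r - i + 1) = (r+1), r, ..., 2
      p[r + 1] <- (m / r) * sum(p[1:r] / seq(r + 1, 2))
    }
  }
  structure(list(m = m, pmf = p, rmax = rmax,
                 tail_mass = max(0, 1 - sum(p))),
            class = "ld_dist")
}

#' @export
print.ld_dist <- function(x, ...) {
  cat("Luria-Delbruck (MSS) distribution: m =", x$m,
      " truncated at r =", x$rmax,
      " tail mass", format(x$tail_mass, digits = 3), "\n")
  invisible(x)
}

#' Log-likelihood of a culture set under the Luria-Delbruck distribution
#'
#' Counts above `r_cap` are capped: they contribute the log upper-tail mass
#' beyond `r_cap` rather than an individual pmf value. Jackpot counts carry
#' little information about `m` beyond "large", and the MSS recursion is
#' O(r^2), so the cap keeps the likelihood cheap and stable.
#'
#' @param cultures a [culture_set()] (or bare integer vector of counts).
#' @param m expected mutational events per culture (>= 0).
#' @param r_cap cap on the count index (default 150).
#' @return The log-likelihood; `-Inf` when `m = 0` and a nonzero count was
#'   observed (an impossible outcome under the model).
#' @export
ld_log_likelihood <- function(cultures, m, r_cap = 150L) {
  counts <- if (inherits(cultures, "culture_set")) cultures$counts else cultures
  if (length(counts) == 0) stop("empty counts")
  if (m < 0) stop("'m' must be non-negative")
  if (m == 0) return(if (any(counts > 0)) -Inf else 0)
  capped <- pmin(counts, r_cap + 1L)      # r_cap + 1 marks "above cap"
  rmax <- min(max(counts), r_cap)
  d <- ld_pmf(m, rmax)
  ll <- 0
  in_range <- capped <= r_cap
  if (any(in_range))
    ll <- ll + sum(log(d$pmf[capped[in_range] + 1L]))
  n_over <- sum(!in_range)
  if (n_over > 0) {
    tail <- max(d$tail_mass, .Machine$double.xmin)
    ll <- ll + n_over * log(tail)
  }
  ll
}

#' Stewart confidence interval for the MSS estimate of m
#'
#' Approximate 95% interval using Stewart's formula for the standard
#' deviation of `ln m`,
#' \deqn{\sigma_{\ln m} = 1.225\, \hat m^{-0.315} / \sqrt{C},}
#' with symmetric limits `exp(ln m_hat +/- 1.96 sigma)`; `C` is the number
#' of parallel cultures.
#'
#' @param m_hat positive MSS point estimate of m.
#' @param n_cultures number of parallel cultures.
#' @return list with `sigma_lnm`, `ci_low`, `ci_high`.
#' @examples
#' mss_confidence_interval(2, 60)
#' @export
mss_confidence_interval <- function(m_hat, n_cultures) {
  if (!is.numeric(m_hat) || m_hat <= 0)
    stop("'m_hat' must be > 0; for all-zero counts use the boundary path ",
         "of fit_mutation_number()")
  if (n_cultures < 1) stop("'n_cultures' must be >= 1")
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(n_cultures)
  list(sigma_lnm = sigma,
       ci_low = exp(log(m_hat) - 1.96 * sigma),
       ci_high = exp(log(m_hat) + 1.96 * sigma))
}

# Lea-Coulson median-based starting value: solve r_med/m - ln(m) = 1.24.
lea_coulson_m0 <- function(r_med) {
  if (r_med <= 0) return(NA_real_)
  f <- function(m) r_med / m - log(m) - 1.24
  tryCatch(uniroot(f, c(1e-8, 1e6))$root, error = function(e) NA_real_)
}

#' Maximum-likelihood estimate of the expected mutational events per culture
#'
#' Maximizes the Ma-Sandri-Sarkar likelihood over `m` by bounded
#' one-dimensional optimization. The starting value comes from the P0
#' method, `m0 = -ln(fraction of zero-count cultures)`, when that fraction
#' is in (0,1), otherwise from the Lea-Coulson median formula; the bracket
#' is widened automatically if the optimum lands on its edge.
#'
#' @param cultures a [culture_set()] (or bare integer vector of counts).
#' @param r_cap cap on the likelihood's count index (see
#'   [ld_log_likelihood()]).
#' @param tol optimization tolerance on m.
#' @return An object of class `rate_estimate`: list with `m_hat`,
#'   `sigma_lnm`, `ci_low`, `ci_high`, `mu` (NA until
#'   [per_division_rate()] is applied), `log_likelihood_at_mle`,
#'   `n_cultures`, `m_init`, and `flags` (character vector; contains
#'   `"all_zero"` for the boundary case `m_hat = 0`, in which case
#'   `m_upper_alpha05` carries the one-sided upper bound
#'   `-ln(0.05)/C` instead of a CI).
#' @examples
#' cs <- sample_from_ld(m = 2, n = 200, seed = 1)
#' fit_mutation_number(culture_set(cs, final_population = 1e8))
#' @export
fit_mutation_number <- function(cultures, r_cap = 150L, tol = 1e-6) {
  counts <- if (inherits(cultures, "culture_set")) cultures$counts else cultures
  n <- length(counts)
  if (n == 0) stop("empty counts")
  if (all(counts == 0)) {
    out <- list(m_hat = 0, sigma_lnm = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, mu = NA_real_,
                log_likelihood_at_mle = 0, n_cultures = n,
                m_init = NA_real_, flags = "all_zero",
                m_upper_alpha05 = -log(0.05) / n)
    return(structure(out, class = "rate_estimate"))
  }
  f0 <- mean(counts == 0)
  m0 <- if (f0 > 0 && f0 < 1) -log(f0) else lea_coulson_m0(stats::median(counts))
  if (!is.finite(m0) || m0 <= 0) m0 <- max(mean(counts), 1)
  upper_global <- 2 * max(mean(counts), 1) * 10
  lo <- max(1e-6, m0 / 50)
  hi <- min(upper_global, m0 * 50)
  if (hi <= lo) { lo <- 1e-6; hi <- upper_global }
  nll <- function(m) ld_log_likelihood(counts, m, r_cap = r_cap)
  repeat {
    opt <- optimize(nll, c(lo, hi), maximum = TRUE, tol = tol)
    edge_lo <- (opt$maximum - lo) < 10 * tol && lo > 1e-6
    edge_hi <- (hi - opt$maximum) < 10 * tol && hi < upper_global
    if (edge_lo) { lo <- max(1e-6, lo / 50) } else
    if (edge_hi) { hi <- min(upper_global, hi * 50) } else break
  }
  m_hat <- opt$maximum
  ci <- mss_confidence_interval(m_hat, n)
  structure(
    list(m_hat = m_hat, sigma_lnm = ci$sigma_lnm,
         ci_low = ci$ci_low, ci_high = ci$ci_high, mu = NA_real_,
         log_likelihood_at_mle = opt$objective, n_cultures = n,
         m_init = m0, flags = character(0)),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("MSS rate estimate: m_hat =", format(x$m_hat, digits = 4))
  if (!"all_zero" %in% x$flags)
    cat("  95% CI [", format(x$ci_low, digits = 4), ",",
        format(x$ci_high, digits = 4), "]")
  if (is.finite(x$mu))
    cat("\n  mu =", format(x$mu, digits = 3), "per cell division",
        " CI [", format(x$mu_ci_low, digits = 3), ",",
        format(x$mu_ci_high, digits = 3), "]")
  if (length(x$flags)) cat("\n  flags:", paste(x$flags, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Final population size from a CFU dilution plate
#'
#' `N_t = colony_count / plated_volume * dilution_factor * culture_volume`.
#'
#' @param colony_count colonies counted on the dilution plate.
#' @param dilution_factor fold dilution before plating (>= 1).
#' @param plated_volume_ml volume of the dilution plated, in ml.
#' @param culture_volume_ml volume of the original culture, in ml.
#' @return `N_t`, CFU per culture; 0 with a warning when no colonies grew.
#' @examples
#' estimate_population_size(40, 1e6, 0.1, 0.25)  # 1e8
#' @export
estimate_population_size <- function(colony_count, dilution_factor,
                                     plated_volume_ml, culture_volume_ml) {
  if (plated_volume_ml <= 0 || culture_volume_ml <= 0)
    stop("volumes must be positive")
  if (dilution_factor < 1) stop("'dilution_factor' must be >= 1")
  if (any(colony_count < 0)) stop("'colony_count' must be non-negative")
  if (any(colony_count == 0))
    warning("zero colonies on the CFU plate: N_t = 0, downstream rate undefined")
  colony_count / plated_volume_ml * dilution_factor * culture_volume_ml
}

#' Per-cell-division mutation rate
#'
#' Converts the expected mutational events per culture into a rate per cell
#' division, `mu = m_hat / N_t`: the number of divisions in a culture grown
#' from a small inoculum is `N_t - N_0 ~ N_t`.
#'
#' @param m_hat MSS estimate of m (>= 0).
#' @param N_t final population size (> 0).
#' @return mutation rate per cell division.
#' @examples
#' per_division_rate(2, 1e8)  # 2e-8
#' @export
per_division_rate <- function(m_hat, N_t) {
  if (any(N_t <= 0)) stop("'N_t' must be positive")
  if (any(m_hat < 0)) stop("'m_hat' must be non-negative")
  m_hat / N_t
}

#' Full mutation-rate estimate for one fluctuation experiment
#'
#' Convenience wrapper: fits m by MSS maximum likelihood, attaches the
#' Stewart CI, and converts m and its CI to per-division rates using the
#' culture set's final population size.
#'
#' @param cultures a [culture_set()].
#' @param ... passed to [fit_mutation_number()].
#' @return A `rate_estimate` with `mu`, `mu_ci_low`, `mu_ci_high` filled in.
#' @export
estimate_mutation_rate <- function(cultures, ...) {
  if (!inherits(cultures, "culture_set"))
    stop("'cultures' must be a culture_set (N_t is required)")
  est <- fit_mutation_number(cultures, ...)
  if (!"all_zero" %in% est$flags) {
    est$mu <- per_division_rate(est$m_hat, cultures$final_population)
    est$mu_ci_low <- est$ci_low / cultures$final_population
    est$mu_ci_high <- est$ci_high / cultures$final_population
  }
  est
}

#' Compare two fluctuation count distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the per-culture mutant counts of
#' two experiments (asymptotic p-value; counts are discrete so ties are
#' expected and the test is conservative).
#'
#' @param a,b [culture_set()] objects or bare count vectors.
#' @return the KS p-value.
#' @export
compare_count_distributions <- function(a, b) {
  ca <- if (inherits(a, "culture_set")) a$counts else a
  cb <- if (inherits(b, "culture_set")) b$counts else b
  if (length(ca) == 0 || length(cb) == 0) stop("empty counts")
  suppressWarnings(ks.test(ca, cb, exact = FALSE))$p.value
}

#' Read fluctuation-assay tables
#'
#' Reads a per-culture counts CSV (`experiment_id, culture_id,
#' selective_count`) and a companion CFU CSV (`experiment_id, cfu_count,
#' dilution_factor, plated_volume_ml, culture_volume_ml`) and returns one
#' [culture_set()] per experiment.
#'
#' @param counts_path,cfu_path CSV file paths.
#' @return named list of `culture_set` objects.
#' @export
read_fluctuation_csv <- function(counts_path, cfu_path) {
  counts <- read.csv(counts_path, stringsAsFactors = FALSE)
  cfu <- read.csv(cfu_path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "culture_id", "selective_count")
  if (!all(need %in% names(counts)))
    stop("counts CSV must have columns: ", paste(need, collapse = ", "))
  need2 <- c("experiment_id", "cfu_count", "dilution_factor",
             "plated_volume_ml", "culture_volume_ml")
  if (!all(need2 %in% names(cfu)))
    stop("cfu CSV must have columns: ", paste(need2, collapse = ", "))
  ids <- unique(counts$experiment_id)
  out <- lapply(ids, function(id) {
    cc <- counts$selective_count[counts$experiment_id == id]
    row <- cfu[cfu$experiment_id == id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("expected exactly one CFU row for experiment '", id, "'")
    nt <- estimate_population_size(row$cfu_count, row$dilution_factor,
                                   row$plated_volume_ml, row$culture_volume_ml)
    culture_set(cc, final_population = nt, label = as.character(id))
  })
  names(out) <- ids
  out
}
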