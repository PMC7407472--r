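#' Simulate a fluctuation assay forward in time
#'
#' Mechanistic generator of jackpot-skewed mutant counts. Each culture
#' grows from `n0` to `nt` cells, for `D = nt - n0` wildtype divisions;
#' every division mutates independently with probability `mu`, so the
#' number of mutational events is Binomial(D, mu) (Poisson(m = mu * nt) in
#' practice). The event's division is uniform over the growth curve, and
#' the mutant clone then expands deterministically at the wildtype rate: a
#' mutation arising when the population has n cells leaves
#' `floor(nt / n)` resistant cells at plating. That final-size law,
#' P(S >= s) = 1/s, is exactly the Luria-Delbruck clone-size distribution
#' underlying the MSS recursion, so the simulated counts match [ld_pmf()]
#' (mutants are assumed neutral, as the estimator assumes).
#'
#' @param mu per-division mutation probability.
#' @param n0 initial cells per culture.
#' @param nt final cells per culture (> n0).
#' @param n_cultures number of parallel cultures.
#' @param seed optional integer seed.
#' @return a [culture_set()] with the simulated counts and
#'   `final_population = nt`.
#' @examples
#' simulate_fluctuation(2e-8, 1e3, 1e8, 20, seed = 1)
#' @export
simulate_fluctuation <- function(mu, n0, nt, n_cultures, seed = NULL) {
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]")
  if (n0 < 1 || nt <= n0) stop("need 1 <= n0 < nt")
  if (!is.null(seed)) set.seed(seed)
  D <- round(nt - n0)
  k_events <- rbinom(n_cultures, size = D, prob = mu)
  counts <- integer(n_cultures)
  total <- sum(k_events)
  if (total > 0) {
    n_at <- n0 + floor(runif(total) * D)     # population size at each event
    sizes <- floor(nt / n_at)
    culture <- rep.int(seq_len(n_cultures), k_events)
    agg <- tapply(sizes, culture, sum)
    counts[as.integer(names(agg))] <- as.integer(agg)
  }
  culture_set(counts, final_population = nt,
              label = sprintf("sim mu=%g", mu))
}

#' Sample mutant counts directly from the MSS distribution
#'
#' Fast i.i.d. draws from [ld_pmf()] for tests; the tail beyond `r_cap` is
#' lumped into the `r_cap` category.
#'
#' @param m expected mutational events per culture.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param r_cap truncation of the pmf.
#' @return integer vector of counts.
#' @export
sample_from_ld <- function(m, n, seed = NULL, r_cap = 150L) {
  if (!is.null(seed)) set.seed(seed)
  if (m == 0) return(integer(n))
  d <- ld_pmf(m, r_cap)
  prob <- d$pmf
  prob[r_cap + 1] <- prob[r_cap + 1] + d$tail_mass
  sample(0:r_cap, size = n, replace = TRUE, prob = prob)
}

#' Standard 48-well plate layout
#'
#' Nine replicates of each of the five mutation-rate conditions plus three
#' blank wells, on an 8 x 6 plate.
#'
#' @return data.frame with `well`, `condition`, `replicate`, `is_blank`.
#' @export
plate_layout_48 <- function() {
  wells <- paste0(rep(LETTERS[1:6], each = 8), rep(1:8, times = 6))
  conditions <- c(rep(c("Low", "LoMid", "Mid", "HiMid", "High"), each = 9),
                  rep("blank", 3))
  data.frame(well = wells, condition = conditions,
             replicate = c(unlist(lapply(1:5, function(i) 1:9)), 1:3),
             is_blank = conditions == "blank", stringsAsFactors = FALSE)
}

two_phase_od <- function(t_hr, rate, od0, od_trans, od_max, beta) {
  t_trans <- log(od_trans / od0) / rate
  ifelse(t_hr < t_trans,
         od0 * exp(rate * t_hr),
         od_max - (od_max - od_trans) * exp(-beta * (t_hr - t_trans)))
}

#' Simulate a day of plate-reader growth curves
#'
#' Each non-blank well grows exponentially from `od0` at `rate` until the
#' transition OD, then relaxes exponentially toward `od_max` at rate
#' `beta`; additive Gaussian reader noise is applied, blanks read a small
#' constant offset plus noise, and with probability `erratic_prob` a well
#' receives a single-sample 50% drop artifact of the kind the erratic-curve
#' detector targets. Defaults emulate the study conditions: 0.85/hr
#' exponential growth, 10-minute sampling over a 23-hour day, an inoculum
#' of a few million CFU in 500 ul (od0 = 1e-3), and an artifact rate of
#' about five traces per thousand.
#'
#' @param layout plate layout (see [plate_layout_48()]).
#' @param day day number attached to the output.
#' @param rate exponential growth rate, 1/hr.
#' @param rate_sd per-well SD of the rate (biological replicate jitter).
#' @param od0 effective inoculum OD600; may be a vector over wells.
#' @param od_trans transition OD between the two phases.
#' @param od_max saturating OD approached late in the day.
#' @param beta saturation-approach rate, 1/hr.
#' @param noise_sd reader noise SD, OD units.
#' @param blank_offset mean OD of blank wells (medium only).
#' @param erratic_prob per-well probability of an injected artifact.
#' @param sampling_min sampling interval, minutes.
#' @param day_hours duration of the day's trace, hours.
#' @param seed optional integer seed.
#' @return long data.frame: `well`, `day`, `condition`, `is_blank`,
#'   `time_min`, `od600`.
#' @export
simulate_growth_plate <- function(layout = plate_layout_48(), day = 1,
                                  rate = 0.85, rate_sd = 0, od0 = 1e-3,
                                  od_trans = 0.2, od_max = 0.45, beta = 0.4,
                                  noise_sd = 0.003, blank_offset = 0.04,
                                  erratic_prob = 0.005, sampling_min = 10,
                                  day_hours = 23, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rate > 0, all(od0 < 0.16), od_max > 0.16, noise_sd >= 0)
  times <- seq(0, day_hours * 60, by = sampling_min)
  t_hr <- times / 60
  od0 <- rep_len(od0, nrow(layout))
  out <- lapply(seq_len(nrow(layout)), function(i) {
    if (layout$is_blank[i]) {
      od <- blank_offset + rnorm(length(times), 0, noise_sd)
    } else {
      r_i <- max(rate + if (rate_sd > 0) rnorm(1, 0, rate_sd) else 0, 0.01)
      clean <- two_phase_od(t_hr, r_i, od0[i], od_trans, od_max, beta)
      od <- clean + blank_offset +
        if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
      if (runif(1) < erratic_prob) {
        # single-sample 50% drop at a clearly measurable OD, the kind of
        # transient reader error the erratic-trace detector targets
        j <- sample(which(clean > 0.1), 1)
        od[j] <- od[j] * 0.5
      }
    }
    data.frame(well = layout$well[i], day = day,
               condition = layout$condition[i],
               is_blank = layout$is_blank[i],
               time_min = times, od600 = od, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default polymorphism-frequency law
#'
#' Mixture mimicking the observed excess of low-frequency polymorphisms:
#' 80% Uniform(0.05, 0.3) and 20% Uniform(0.3, 1).
#'
#' @param n number of draws.
#' @return frequencies in \[0.05, 1\].
#' @export
rfrequency_default <- function(n) {
  low <- runif(n) < 0.8
  ifelse(low, runif(n, 0.05, 0.3), runif(n, 0.3, 1))
}

#' Simulate mutation-call tables with planted structure
#'
#' Generates the inputs the variant filters and the cluster scan assume:
#' uniform background calls per sample and mutation type, optional gene
#' clusters planted in stated regions, ancestral calls present in the
#' ancestor table and copied into every sample, and calls duplicated
#' across two wells (standing variation masquerading as recurrence).
#' Frequencies are drawn from `frequency_law` and floored at 0.05, the
#' polymorphism calling cutoff. Background intensities default to the
#' study's scale: roughly 20 substitutions and about one deletion per
#' sample, with insertions and mobile-element events rarer still.
#'
#' @param samples data.frame with `well`, `day`, `condition`, one row per
#'   sequenced sample.
#' @param genome_length reference length, bp.
#' @param per_sample_intensity named vector: expected background calls per
#'   sample for each mutation type.
#' @param planted optional data.frame with `start`, `end`, `mtype`, `k`:
#'   each row plants `k` distinct mutations of `mtype` at distinct uniform
#'   positions inside \[start, end\], each assigned to a random sample.
#' @param n_ancestral number of ancestral calls (in the ancestor table and
#'   every sample).
#' @param n_shared number of calls duplicated across two random wells.
#' @param frequency_law function(n) returning frequencies.
#' @param seed optional integer seed.
#' @return list with `table` (all samples, a [mutation_table()]),
#'   `ancestor` (the ancestor's table), and `truth` (list of the planted,
#'   ancestral and shared record data.frames for checking filters).
#' @export
simulate_mutation_tables <- function(samples, genome_length = 4641652,
                                     per_sample_intensity =
                                       c(SNP = 20, DEL = 0.9, INS = 0.45,
                                         MOB = 0.075),
                                     planted = NULL, n_ancestral = 0,
                                     n_shared = 0,
                                     frequency_law = rfrequency_default,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(per_sample_intensity >= 0))
  bases <- c("A", "C", "G", "T")
  new_allele <- function(mtype, n) switch(
    mtype,
    SNP = paste0(sample(bases, n, TRUE), ">",
                 sample(bases, n, TRUE)),
    DEL = rep("del1", n),
    INS = paste0("ins", sample(bases, n, TRUE)),
    MOB = rep("IS1:1", n))
  rec <- function(well, day, condition, mtype, position, allele, frequency)
    data.frame(well = well, day = day, condition = condition, mtype = mtype,
               position = position, size = 1L, allele = allele,
               frequency = pmax(frequency, 0.05), stringsAsFactors = FALSE)
  all_recs <- list()
  # background: uniform positions, per-sample Poisson counts
  for (i in seq_len(nrow(samples))) {
    for (mt in names(per_sample_intensity)) {
      n <- rpois(1, per_sample_intensity[[mt]])
      if (n == 0) next
      all_recs[[length(all_recs) + 1L]] <-
        rec(samples$well[i], samples$day[i], samples$condition[i], mt,
            sample.int(genome_length, n), new_allele(mt, n),
            frequency_law(n))
    }
  }
  truth <- list(planted = NULL, ancestral = NULL, shared = NULL)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      if (planted$start[i] < 1 || planted$end[i] > genome_length)
        stop("planted region outside the genome")
      k <- planted$k[i]
      pos <- planted$start[i] - 1L +
        sample.int(planted$end[i] - planted$start[i] + 1L, k)
      s <- sample.int(nrow(samples), k, replace = TRUE)
      r <- rec(samples$well[s], samples$day[s], samples$condition[s],
               planted$mtype[i], pos, new_allele(planted$mtype[i], k),
               frequency_law(k))
      all_recs[[length(all_recs) + 1L]] <- r
      truth$planted <- rbind(truth$planted, r)
    }
  }
  anc_recs <- NULL
  if (n_ancestral > 0) {
    pos <- sample.int(genome_length, n_ancestral)
    allele <- new_allele("SNP", n_ancestral)
    anc_recs <- rec("ancestor", 0, "ancestor", "SNP", pos, allele,
                    frequency_law(n_ancestral))
    for (i in seq_len(nrow(samples))) {
      r <- rec(samples$well[i], samples$day[i], samples$condition[i],
               "SNP", pos, allele, frequency_law(n_ancestral))
      all_recs[[length(all_recs) + 1L]] <- r
      truth$ancestral <- rbind(truth$ancestral, r)
    }
  }
  if (n_shared > 0) {
    wells <- unique(samples$well)
    if (length(wells) < 2) stop("shared calls need at least two wells")
    for (j in seq_len(n_shared)) {
      pos <- sample.int(genome_length, 1)
      allele <- new_allele("SNP", 1)
      pick <- sample(wells, 2)
      for (wl in pick) {
        s <- which(samples$well == wl)[1]
        r <- rec(wl, samples$day[s], samples$condition[s], "SNP", pos,
                 allele, frequency_law(1))
        all_recs[[length(all_recs) + 1L]] <- r
        truth$shared <- rbind(truth$shared, r)
      }
    }
  }
  recs <- do.call(rbind, all_recs)
  # de-duplicate identical (sample, mtype, position, allele) collisions
  recs <- recs[!duplicated(paste(recs$well, recs$day, recs$mtype,
                                 recs$position, recs$allele)), ]
  list(table = mutation_table(recs, genome_length, "simulated"),
       ancestor = mutation_table(
         if (is.null(anc_recs))
           data.frame(well = character(0), mtype = character(0),
                      position = integer(0))
         else anc_recs,
         genome_length, "simulated ancestor"),
       truth = truth)
}

#' Simulate a noisy dose-response series
#'
#' `y = eval_hill(fit, x) * (1 + eps)` with `eps ~ Normal(0, noise_cv^2)`:
#' multiplicative noise, matching measurements whose uncertainty scales
#' with their magnitude.
#'
#' @param fit a [hill_fit()] used as the generating truth.
#' @param grid non-negative concentrations.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed optional integer seed.
#' @return data.frame with `x` and `y`.
#' @export
simulate_dose_response <- function(fit, grid, noise_cv = 0, seed = NULL) {
  if (any(grid < 0)) stop("'grid' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  y <- eval_hill(fit, grid)
  if (noise_cv > 0) y <- y * (1 + rnorm(length(grid), 0, noise_cv))
  data.frame(x = grid, y = y)
}
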