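#' Monte-Carlo scan statistic for mutation clustering
#'
#' Tail probability that, when `n_mutations` positions fall uniformly at
#' random on a genome of `genome_length` bases, some window of `window`
#' consecutive bases contains at least `threshold` of them. Scanning every
#' window is what corrects for the multiple comparisons implicit in
#' searching the whole genome for mutation clusters. Each replicate draws
#' the positions (with replacement; coincident draws are ~N^2/2G and count
#' as distinct), sorts them, and succeeds iff some `threshold` consecutive
#' order statistics span at most `window - 1` bases.
#'
#' Exact shortcuts skip the simulation: `threshold > n_mutations` gives
#' p = 0, `threshold = 1` gives p = 1 (any point is a cluster of one), and
#' `window >= genome_length` gives p = 1.
#'
#' @param n_mutations total mutations of the type under test, N.
#' @param window window (gene/operon) length in bp, w.
#' @param threshold observed distinct mutation count, k (>= 1).
#' @param genome_length genome length G in bp (default: MG1655 chromosome).
#' @param circular wrap windows past the origin? (Default linear; at the
#'   w/G of genes the difference is negligible.)
#' @param reps Monte-Carlo replicates.
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   successes are bit-identical across runs.
#' @return object of class `scan_result`: list with `p_mc`, `mc_se`
#'   (binomial SE), `successes`, `reps_used`, `p_analytic` (see
#'   [scan_pvalue_analytic()]; `NA` where invalid), `exact` (TRUE when a
#'   shortcut fired), and the configuration.
#' @examples
#' scan_pvalue_mc(40, 1221, 3, reps = 1e4, seed = 1)
#' @export
scan_pvalue_mc <- function(n_mutations, window, threshold,
                           genome_length = 4641652, circular = FALSE,
                           reps = 1e6, seed = NULL) {
  stopifnot(n_mutations >= 1, window >= 1, threshold >= 1, reps >= 1,
            window <= genome_length)
  cfg <- list(n_mutations = as.integer(n_mutations),
              window = as.integer(window),
              threshold = as.integer(threshold),
              genome_length = genome_length, circular = circular,
              reps = as.integer(reps), seed = seed)
  p_an <- if (window / genome_length > 0.1) NA_real_ else
    scan_pvalue_analytic(n_mutations, window, threshold, genome_length)
  finish <- function(p, successes, reps_used, exact) {
    structure(list(p_mc = p,
                   mc_se = if (reps_used > 0)
                     sqrt(p * (1 - p) / reps_used) else 0,
                   successes = successes, reps_used = reps_used,
                   p_analytic = p_an, exact = exact, config = cfg),
              class = "scan_result")
  }
  if (threshold > n_mutations) return(finish(0, 0L, 0L, TRUE))
  if (threshold == 1) return(finish(1, 0L, 0L, TRUE))
  if (window >= genome_length) return(finish(1, 0L, 0L, TRUE))
  if (!is.null(seed)) set.seed(seed)
  succ <- scan_mc_cpp(genome_length, as.integer(n_mutations),
                      as.integer(window), as.integer(threshold),
                      as.integer(reps), circular)
  finish(succ / reps, succ, as.integer(reps), FALSE)
}

#' @export
print.scan_result <- function(x, ...) {
  cfg <- x$config
  cat("Window scan: N =", cfg$n_mutations, " w =", cfg$window,
      " k =", cfg$threshold, " G =", format(cfg$genome_length), "\n")
  if (x$exact) {
    cat("  p =", x$p_mc, "(exact shortcut)\n")
  } else {
    cat("  p_mc =", format(x$p_mc, digits = 3),
        "+/-", format(x$mc_se, digits = 2),
        " (", x$successes, "/", x$reps_used, "replicates )\n")
  }
  if (is.finite(x$p_analytic))
    cat("  analytic cross-check:", format(x$p_analytic, digits = 3), "\n")
  invisible(x)
}

#' Analytic cross-check for the window scan
#'
#' Expected-cluster approximation: with `q = w/G`, the expected number of
#' k-point subsets whose range is at most w is
#' \deqn{E = \binom{N}{k}\left[k q^{k-1} - (k-1) q^k\right],}
#' and the returned value is `1 - exp(-E)`. This is an order-of-magnitude
#' corroboration of the Monte-Carlo value, accurate when both `E` and
#' `N w / G` are small; when `N w / G` is appreciable, clusters tend to
#' contain extra points, each of which multiplies the subset count, so the
#' approximation overshoots the true tail probability (by less than a
#' factor of 2 in the regimes exercised here).
#'
#' @inheritParams scan_pvalue_mc
#' @return the approximate tail probability; 0 when `threshold >
#'   n_mutations`. Warns when `w/G` is too large for the approximation.
#' @examples
#' scan_pvalue_analytic(1000, 1488, 8)
#' @export
scan_pvalue_analytic <- function(n_mutations, window, threshold,
                                 genome_length = 4641652) {
  if (threshold > n_mutations) return(0)
  if (threshold < 2) return(NA_real_)
  q <- window / genome_length
  if (q > 0.1) {
    warning("w/G = ", format(q, digits = 2),
            " is too large for the expected-cluster approximation")
    return(NA_real_)
  }
  k <- threshold
  log_term <- log(k) + (k - 1) * log(q) + log1p(-(k - 1) / k * q)
  E <- exp(lchoose(n_mutations, k) + log_term)
  -expm1(-E)
}

#' Count distinct mutations per gene
#'
#' Distinct (position, allele) pairs of one mutation type in each annotated
#' gene, with the gene length; the per-gene input of the cluster scan.
#' Recurrences of the same mutation (same position and allele) within a
#' well count once.
#'
#' @param table a filtered [mutation_table()].
#' @param annotation data.frame with `gene`, `start`, `end`.
#' @param mtype one of `"SNP"`, `"DEL"`, `"INS"`, `"MOB"`.
#' @param drop_empty omit genes with zero mutations? (default TRUE).
#' @return data.frame: `gene`, `length`, `count`.
#' @export
unique_mutations_per_gene <- function(table, annotation, mtype = "SNP",
                                      drop_empty = TRUE) {
  if (nrow(annotation) == 0) stop("empty annotation")
  sub <- table[table$mtype == mtype, ]
  sub <- sub[!duplicated(paste(sub$position, sub$allele)), ]
  out <- data.frame(gene = annotation$gene,
                    length = annotation$end - annotation$start + 1L,
                    count = vapply(seq_len(nrow(annotation)), function(i) {
                      s <- annotation$start[i]; e <- annotation$end[i]
                      sum(sub$position + sub$size - 1L >= s & sub$position <= e)
                    }, integer(1)),
                    stringsAsFactors = FALSE)
  if (drop_empty) out <- out[out$count > 0, ]
  rownames(out) <- NULL
  out
}

#' Genome-wide cluster significance report
#'
#' For every gene (or user region, e.g. an operon span) carrying at least
#' two distinct mutations of a type, runs the Monte-Carlo window scan with
#' N equal to the genome-wide total of distinct mutations of that type, w
#' the gene length, and k the gene's distinct count, and reports the
#' Monte-Carlo and analytic tail probabilities.
#'
#' @param table a filtered [mutation_table()].
#' @param annotation data.frame with `gene`, `start`, `end`.
#' @param mtypes mutation types to scan.
#' @param regions optional extra intervals (same columns as `annotation`)
#'   tested alongside the genes.
#' @param genome_length genome length; defaults to the table's reference.
#' @param reps Monte-Carlo replicates per gene.
#' @param seed optional seed (applied once, before the first gene).
#' @param round_up_N round each genome-wide total up to one significant
#'   figure (e.g. 35 -> 40), a conservative null; supply `n_total` for any
#'   other convention (e.g. promoting 825 substitutions to 1000).
#' @param n_total optional named vector overriding N per mutation type.
#' @return data.frame sorted by `p_mc`: `gene`, `mtype`, `k`, `w`, `N`,
#'   `p_mc`, `mc_se`, `p_analytic`. Zero rows when no gene has >= 2
#'   mutations of any requested type.
#' @export
gene_cluster_report <- function(table, annotation,
                                mtypes = c("SNP", "DEL", "INS", "MOB"),
                                regions = NULL, genome_length = NULL,
                                reps = 1e5, seed = NULL,
                                round_up_N = FALSE, n_total = NULL) {
  if (is.null(genome_length)) genome_length <- ref_len(table)
  ann <- rbind(annotation[c("gene", "start", "end")],
               if (!is.null(regions)) regions[c("gene", "start", "end")])
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (mt in mtypes) {
    sub <- table[table$mtype == mt, ]
    N <- sum(!duplicated(paste(sub$position, sub$allele)))
    if (!is.null(n_total) && mt %in% names(n_total)) {
      N <- n_total[[mt]]
    } else if (round_up_N && N > 0) {
      mag <- 10^floor(log10(N))
      N <- as.integer(ceiling(N / mag) * mag)
    }
    if (N < 2) next
    per_gene <- unique_mutations_per_gene(table, ann, mt)
    per_gene <- per_gene[per_gene$count >= 2, ]
    for (i in seq_len(nrow(per_gene))) {
      res <- scan_pvalue_mc(N, per_gene$length[i], per_gene$count[i],
                            genome_length = genome_length, reps = reps)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = per_gene$gene[i], mtype = mt,
                   k = per_gene$count[i], w = per_gene$length[i], N = N,
                   p_mc = res$p_mc, mc_se = res$mc_se,
                   p_analytic = res$p_analytic, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), mtype = character(0),
                      k = integer(0), w = integer(0), N = integer(0),
                      p_mc = numeric(0), mc_se = numeric(0),
                      p_analytic = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p_mc), ]
  rownames(out) <- NULL
  out
}
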