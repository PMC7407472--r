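test_that("GenomeDiff mutation lines parse; evidence lines are skipped", {
  gd <- tempfile(fileext = ".gd")
  writeLines(c("#=GENOME_DIFF\t1.0",
               "#=TITLE\tsample1",
               "SNP\t1\t10\tNC_000913.3\t100\tA\tfrequency=0.25",
               "DEL\t2\t11\tNC_000913.3\t5000\t120\tfrequency=1",
               "RA\t10\t.\tNC_000913.3\t100\t0\tG\tA"), gd)
  tab <- read_genomediff(gd, well = "w1", day = 24)
  expect_equal(nrow(tab), 2)
  snp <- tab[tab$mtype == "SNP", ]
  expect_equal(snp$position, 100L)
  expect_equal(snp$frequency, 0.25)
  expect_equal(tab$size[tab$mtype == "DEL"], 120L)

  # evidence-only file: empty table
  gd2 <- tempfile(fileext = ".gd")
  writeLines(c("#=GENOME_DIFF\t1.0",
               "RA\t1\t.\tNC_000913.3\t10\t0\tG\tA",
               "MC\t2\t.\tNC_000913.3\t5\t9\t0\t0",
               "JC\t3\t.\tNC_000913.3\t1\t1\tNC_000913.3\t9\t1\t0"), gd2)
  expect_equal(nrow(read_genomediff(gd2)), 0)

  # missing frequency defaults to a consensus call
  gd3 <- tempfile(fileext = ".gd")
  writeLines(c("#=GENOME_DIFF\t1.0",
               "SNP\t1\t10\tNC_000913.3\t42\tT"), gd3)
  expect_equal(read_genomediff(gd3)$frequency, 1.0)

  gd4 <- tempfile(fileext = ".gd")
  writeLines(c("#=GENOME_DIFF\t1.0",
               "SNP\t1\t10\tNC_000913.3\toops\tA"), gd4)
  expect_error(read_genomediff(gd4), "non-numeric position")
  notgd <- tempfile()
  writeLines("hello", notgd)
  expect_error(read_genomediff(notgd), "GENOME_DIFF")
})

test_that("GenomeDiff writing round-trips through the reader", {
  sim <- simulate_mutation_tables(
    data.frame(well = "A1", day = 24, condition = "High"),
    per_sample_intensity = c(SNP = 15, DEL = 2, INS = 1, MOB = 0.5),
    seed = 8)
  path <- tempfile(fileext = ".gd")
  write_genomediff(sim$table, path)
  back <- read_genomediff(path, well = "A1", day = 24, condition = "High")
  expect_equal(sorted_keys(back), sorted_keys(sim$table))
  expect_equal(sort(back$frequency), sort(sim$table$frequency))
})

test_that("ancestral filter removes matches at any frequency", {
  tab <- mutation_table(rbind(mut_rec("A1", 100, freq = 0.9),
                              mut_rec("A1", 200, freq = 0.9),
                              mut_rec("A1", 300, freq = 0.5)), 1e6)
  anc <- mutation_table(mut_rec("anc", 200, freq = 0.06), 1e6)
  out <- filter_ancestral(tab, anc)
  expect_equal(out$position, c(100L, 300L))

  # empty ancestor: identity
  anc0 <- mutation_table(data.frame(well = character(0),
                                    mtype = character(0),
                                    position = integer(0)), 1e6)
  expect_equal(nrow(filter_ancestral(tab, anc0)), 3)
  anc_wrong <- mutation_table(mut_rec("anc", 200), 2e6)
  expect_error(filter_ancestral(tab, anc_wrong), "reference length")
})

test_that("shared-well filter drops cross-well recurrences but keeps timepoints", {
  tab <- mutation_table(rbind(
    mut_rec("A1", 100, day = 24),          # shared across wells -> dropped
    mut_rec("A2", 100, day = 24),
    mut_rec("A1", 500, day = 24),          # same well, two days -> kept
    mut_rec("A1", 500, day = 41),
    mut_rec("A3", 900, day = 24)), 1e6)    # unique -> kept
  out <- filter_shared_wells(tab)
  expect_equal(sort(unique(out$position)), c(500L, 900L))
  expect_equal(sum(out$position == 500), 2)

  uniq <- mutation_table(rbind(mut_rec("A1", 1), mut_rec("A2", 2)), 1e6)
  expect_equal(nrow(filter_shared_wells(uniq)), 2)
})

test_that("filters are idempotent and commute on planted tables", {
  sim <- simulate_mutation_tables(
    data.frame(well = c("A1", "A2", "A3", "A4"), day = 24,
               condition = "High"),
    per_sample_intensity = c(SNP = 12, DEL = 1, INS = 0.5, MOB = 0.1),
    n_ancestral = 6, n_shared = 4, seed = 9)
  t1 <- filter_shared_wells(filter_ancestral(sim$table, sim$ancestor))
  t2 <- filter_ancestral(filter_shared_wells(sim$table), sim$ancestor)
  expect_equal(sorted_keys(t1), sorted_keys(t2))
  expect_equal(sorted_keys(filter_shared_wells(t1)), sorted_keys(t1))
  expect_equal(sorted_keys(filter_ancestral(t1, sim$ancestor)),
               sorted_keys(t1))
  expect_lte(nrow(t1), nrow(sim$table))
})

test_that("cumulative curves count SNPs at or above each grid frequency", {
  tab <- mutation_table(rbind(
    mut_rec("A1", 1, freq = 1.0), mut_rec("A1", 2, freq = 0.6),
    mut_rec("A1", 3, freq = 0.3), mut_rec("A1", 4, freq = 0.07),
    mut_rec("A1", 6, mtype = "DEL", allele = "del1", freq = 0.9)), 1e6)
  cv <- cumulative_snp_curve(tab, well = "A1")
  expect_equal(cv$count[1], 1)                       # f = 1.0
  expect_equal(cv$count[which.min(abs(cv$freq - 0.5))], 2)
  expect_equal(cv$count[nrow(cv)], 4)                # f = 0.05; DEL excluded
  expect_true(all(diff(cv$count) >= 0))

  empty <- cumulative_snp_curve(tab, well = "nope")
  expect_true(all(empty$count == 0))
})

test_that("condition mean curves carry pointwise mean and SEM", {
  g <- seq(1, 0.05, length.out = 10)
  mk <- function(v) structure(data.frame(freq = g, count = v),
                              class = c("cumulative_curve", "data.frame"))
  out <- condition_mean_curve(list(mk(rep(1, 10)), mk(rep(3, 10))), c("H", "H"))
  expect_equal(out$mean, rep(2, 10))
  expect_equal(out$sem, rep(sd(c(1, 3)) / sqrt(2), 10))  # = 1

  single <- condition_mean_curve(list(mk(rep(5, 10))), "L")
  expect_equal(single$mean, rep(5, 10))
  expect_equal(single$sem, rep(0, 10))
  expect_equal(single$n, rep(1, 10))

  bad <- structure(data.frame(freq = g[1:5], count = 1:5),
                   class = c("cumulative_curve", "data.frame"))
  expect_error(condition_mean_curve(list(mk(rep(1, 10)), bad), c("a", "b")),
               "common")
})

test_that("tripled SNP intensity triples the mean cumulative totals", {
  samples <- function(cond) data.frame(well = paste0(cond, 1:4), day = 41,
                                       condition = cond)
  hi <- simulate_mutation_tables(samples("H"),
                                 per_sample_intensity = c(SNP = 30),
                                 seed = 21)$table
  lo <- simulate_mutation_tables(samples("L"),
                                 per_sample_intensity = c(SNP = 10),
                                 seed = 22)$table
  curves <- c(lapply(paste0("H", 1:4), function(w)
                cumulative_snp_curve(hi, well = w)),
              lapply(paste0("L", 1:4), function(w)
                cumulative_snp_curve(lo, well = w)))
  m <- condition_mean_curve(curves, rep(c("High", "Low"), each = 4))
  tot <- function(cond) {
    sub <- m[m$condition == cond, ]
    sub$mean[which.min(sub$freq)]   # total retained SNPs per sample
  }
  expect_equal(tot("High") / tot("Low"), 3, tolerance = 0.25)
})

test_that("gene annotation uses 1-based inclusive intervals and spans", {
  ann <- data.frame(gene = c("gA", "gB"), start = c(100L, 180L),
                    end = c(200L, 260L))
  tab <- mutation_table(rbind(
    mut_rec("A1", 150),
    mut_rec("A1", 200),                                 # boundary inclusive
    mut_rec("A1", 201),                                 # just outside gA
    mut_rec("A1", 170, mtype = "DEL", allele = "del40", size = 40L)), 1e6)
  out <- annotate_genes(tab, ann)
  expect_equal(out$gene[out$position == 150], "gA")
  expect_equal(out$gene[out$position == 200], "gA,gB")
  expect_equal(out$gene[out$position == 201], "gB")
  expect_equal(out$gene[out$mtype == "DEL"], "gA,gB")   # span 170-209
  expect_error(annotate_genes(tab, data.frame(gene = "x", start = 1,
                                              end = 2e6)),
               "beyond")
})

test_that("GFF3 and BED annotation readers agree on coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr", "src", "gene", "101", "200", ".", "+", ".",
                     "ID=g1;Name=sufB", sep = "\t"),
               paste("chr", "src", "gene", "501", "700", ".", "-", ".",
                     "ID=g2", sep = "\t")), gff)
  a <- read_gene_annotation(gff)
  expect_equal(a$gene, c("sufB", "g2"))
  expect_equal(a$start, c(101L, 501L))
  expect_equal(a$end, c(200L, 700L))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr\t100\t200\tsufB", "chr\t500\t700\tg2"), bed)
  b <- read_gene_annotation(bed, format = "bed")
  expect_equal(b[c("gene", "start", "end")], a[c("gene", "start", "end")])
})

test_that("mutation_table enforces its invariants", {
  expect_error(mutation_table(mut_rec("A1", 0), 1e6), "1-based")
  expect_error(mutation_table(mut_rec("A1", 2e6), 1e6), "beyond")
  expect_error(mutation_table(mut_rec("A1", 5, freq = 1.5), 1e6),
               "frequency")
  expect_error(mutation_table(mut_rec("A1", 5, mtype = "INV"), 1e6),
               "mtype")
  expect_error(mutation_table(rbind(mut_rec("A1", 5), mut_rec("A1", 5)),
                              1e6),
               "duplicate")
})
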