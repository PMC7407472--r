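MUTATION_TYPES <- c("SNP", "DEL", "INS", "MOB")

#' Construct a mutation-call table
#'
#' A thin data.frame container for typed, positioned, frequency-annotated
#' mutation calls keyed by sample (well, day, condition). Columns: `well`,
#' `day`, `condition`, `mtype` (SNP/DEL/INS/MOB), `position` (1-based),
#' `size` (bases affected; 1 for SNPs), `allele` (ref>alt or event
#' description), `gene`, `frequency` in \[0, 1\].
#'
#' @param records data.frame with at least `well`, `mtype`, `position`;
#'   missing `day`/`condition`/`size`/`allele`/`gene`/`frequency` columns
#'   are filled with defaults (`frequency` 1.0, `size` 1).
#' @param reference_length reference chromosome length in bp.
#' @param provenance free text.
#' @return object of class `mutation_table` (a data.frame with attributes
#'   `reference_length` and `provenance`).
#' @export
mutation_table <- function(records, reference_length, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0) {
    for (col in c("well", "mtype", "position"))
      if (!col %in% names(records)) stop("records must have column '", col, "'")
  } else {
    records <- data.frame(well = character(0), mtype = character(0),
                          position = integer(0), stringsAsFactors = FALSE)
  }
  defaults <- list(day = NA_integer_, condition = NA_character_, size = 1L,
                   allele = NA_character_, gene = NA_character_,
                   frequency = 1.0)
  for (col in names(defaults))
    if (!col %in% names(records))
      records[[col]] <- rep(defaults[[col]], nrow(records))
  if (nrow(records) > 0) {
    if (!all(records$mtype %in% MUTATION_TYPES))
      stop("mtype must be one of ", paste(MUTATION_TYPES, collapse = ", "))
    if (any(records$position < 1)) stop("positions are 1-based (>= 1)")
    if (any(records$position > reference_length))
      stop("position beyond reference_length")
    if (any(records$frequency < 0 | records$frequency > 1))
      stop("frequency must be in [0, 1]")
    key <- paste(records$well, records$day, records$mtype,
                 records$position, records$allele)
    if (anyDuplicated(key))
      stop("duplicate (sample, mtype, position, allele) records")
  }
  records <- records[c("well", "day", "condition", "mtype", "position",
                       "size", "allele", "gene", "frequency")]
  structure(records, reference_length = as.integer(reference_length),
            provenance = provenance,
            class = c("mutation_table", "data.frame"))
}

ref_len <- function(table) attr(table, "reference_length")

mutation_key <- function(table) {
  paste(table$mtype, table$position, table$allele, sep = "\r")
}

rebuild_table <- function(records, template) {
  mutation_table(records, reference_length = ref_len(template),
                 provenance = attr(template, "provenance"))
}

#' Read a breseq GenomeDiff file
#'
#' Parses the mutation lines (SNP, DEL, INS, MOB) of a GenomeDiff (GD)
#' file; evidence lines (RA, MC, JC, UN) and header metadata are skipped.
#' The `frequency=` field is read when present and defaults to 1.0 (a
#' consensus call). Positions are 1-based as in the format.
#'
#' @param path GD file path.
#' @param well,day,condition sample labels attached to every record (the GD
#'   format itself is one sample per file).
#' @param reference_length reference chromosome length (default: the
#'   MG1655 chromosome, 4,641,652 bp).
#' @return a [mutation_table()].
#' @export
read_genomediff <- function(path, well = basename(path), day = NA,
                            condition = NA, reference_length = 4641652) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^#=GENOME_DIFF", lines[1]))
    stop("not a GenomeDiff file (missing '#=GENOME_DIFF' header): ", path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  recs <- list()
  for (idx in seq_along(lines)) {
    f <- strsplit(lines[idx], "\t", fixed = TRUE)[[1]]
    type <- f[1]
    if (!type %in% MUTATION_TYPES) next  # evidence / validation lines
    if (length(f) < 5)
      stop("malformed ", type, " line (", length(f), " fields): ", lines[idx])
    pos <- suppressWarnings(as.integer(f[5]))
    if (is.na(pos))
      stop("non-numeric position in GD line: ", lines[idx])
    kv <- f[grepl("=", f, fixed = TRUE)]
    keyvals <- strsplit(kv, "=", fixed = TRUE)
    freq <- 1.0
    for (p in keyvals)
      if (length(p) == 2 && p[1] == "frequency")
        freq <- as.numeric(p[2])
    size <- 1L
    allele <- switch(type,
      SNP = f[6],
      DEL = { size <- as.integer(f[6]); paste0("del", f[6]) },
      INS = paste0("ins", f[6]),
      MOB = paste(f[6], f[7], sep = ":"))
    recs[[length(recs) + 1L]] <-
      data.frame(well = well, day = day, condition = condition,
                 mtype = type, position = pos, size = size,
                 allele = allele, frequency = freq,
                 stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(well = character(0), mtype = character(0),
               position = integer(0))
  mutation_table(records, reference_length = reference_length,
                 provenance = path)
}

#' Write mutation records to a GenomeDiff file
#'
#' Inverse of [read_genomediff()] for the supported mutation types; one
#' sample (one `well`/`day`) per file.
#'
#' @param table a [mutation_table()] containing a single sample.
#' @param path output file.
#' @param seq_id reference sequence name written on each line.
#' @return `path`, invisibly.
#' @export
write_genomediff <- function(table, path, seq_id = "NC_000913.3") {
  if (nrow(table) > 0 &&
      nrow(unique(table[c("well", "day")])) > 1)
    stop("GenomeDiff files hold one sample; filter to one (well, day) first")
  lines <- "#=GENOME_DIFF\t1.0"
  if (nrow(table) > 0) {
    for (i in seq_len(nrow(table))) {
      r <- table[i, ]
      spec <- switch(r$mtype,
        SNP = r$allele,
        DEL = as.character(r$size),
        INS = sub("^ins", "", r$allele),
        MOB = paste(strsplit(r$allele, ":", fixed = TRUE)[[1]][1:2],
                    collapse = "\t"))
      lines <- c(lines, paste(r$mtype, i, "", seq_id, r$position, spec,
                              paste0("frequency=", r$frequency),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Remove mutations present in the ancestor
#'
#' Drops every record whose (mtype, position, allele) identity appears in
#' the ancestor table at any frequency, focusing the analysis on mutations
#' that arose de novo during the experiment.
#'
#' @param table,ancestor [mutation_table()] objects on the same reference.
#' @return the filtered table.
#' @export
filter_ancestral <- function(table, ancestor) {
  if (ref_len(table) != ref_len(ancestor))
    stop("reference length mismatch between table and ancestor")
  keep <- !(mutation_key(table) %in% mutation_key(ancestor))
  rebuild_table(table[keep, ], table)
}

#' Remove mutations shared across wells
#'
#' Drops every (mtype, position, allele) identity observed in more than one
#' distinct well: such recurrences are almost certainly low-frequency
#' standing variation in the ancestor rather than independent de novo
#' events. The two sequenced timepoints of the same well count as one well,
#' so within-well recurrence across days is retained.
#'
#' @param table a [mutation_table()].
#' @return the filtered table.
#' @export
filter_shared_wells <- function(table) {
  if (nrow(table) == 0) return(table)
  key <- mutation_key(table)
  wells_per_key <- tapply(table$well, key, function(w) length(unique(w)))
  keep <- wells_per_key[key] <= 1
  rebuild_table(table[keep, ], table)
}

#' Cumulative SNP count vs polymorphism frequency
#'
#' For one sample, counts the SNPs with frequency at or above each value of
#' a descending grid from fixation (1.0) down to the calling cutoff
#' (default 5%, below which polymorphisms are not called at ~50x
#' coverage). The curve is non-decreasing as frequency falls; its value at
#' `min_freq` is the sample's total retained SNP count.
#'
#' @param table a filtered [mutation_table()].
#' @param well,day select the sample; `NULL` uses all records in `table`.
#' @param min_freq lower frequency cutoff (default 0.05).
#' @param grid_points number of evenly spaced grid values.
#' @return object of class `cumulative_curve`: data.frame with descending
#'   `freq` and `count`.
#' @export
cumulative_snp_curve <- function(table, well = NULL, day = NULL,
                                 min_freq = 0.05, grid_points = 200) {
  sub <- table[table$mtype == "SNP", ]
  if (!is.null(well)) sub <- sub[sub$well == well, ]
  if (!is.null(day)) sub <- sub[!is.na(sub$day) & sub$day == day, ]
  grid <- seq(1, min_freq, length.out = grid_points)
  counts <- vapply(grid, function(f) sum(sub$frequency >= f), integer(1))
  structure(data.frame(freq = grid, count = counts),
            class = c("cumulative_curve", "data.frame"))
}

#' Mean cumulative curve with SEM band per condition
#'
#' Pointwise mean and standard error of the mean (SD / sqrt(n)) of
#' cumulative SNP curves across the samples of each condition; the smoother
#' per-condition estimate of how SNP burden varies with mutation rate.
#'
#' @param curves list of [cumulative_snp_curve()] results on a common grid.
#' @param condition character vector, one condition label per curve.
#' @return data.frame: `condition`, `freq`, `mean`, `sem`, `n`. `sem` is 0
#'   with `n = 1` when a condition has a single curve.
#' @export
condition_mean_curve <- function(curves, condition) {
  if (length(curves) != length(condition))
    stop("'condition' must label each curve")
  grid <- curves[[1]]$freq
  for (cv in curves)
    if (!isTRUE(all.equal(cv$freq, grid)))
      stop("curves are not on a common frequency grid")
  out <- lapply(unique(condition), function(cond) {
    mat <- vapply(curves[condition == cond], function(cv) cv$count,
                  numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    n <- ncol(mat)
    data.frame(condition = cond, freq = grid,
               mean = rowMeans(mat),
               sem = if (n > 1) apply(mat, 1, sd) / sqrt(n) else 0,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign gene annotations to mutation records
#'
#' Sets each record's `gene` to the gene(s) whose 1-based inclusive
#' interval covers it; records in overlapping genes get all covering genes
#' (comma-separated) and intergenic records stay `NA`. Deletions use their
#' full span, so a deletion crossing several genes is annotated with each.
#'
#' @param table a [mutation_table()].
#' @param annotation data.frame with `gene`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_gene_annotation()].
#' @return the annotated table.
#' @export
annotate_genes <- function(table, annotation) {
  need <- c("gene", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (any(annotation$end > ref_len(table)))
    stop("annotation interval beyond reference_length")
  if (any(annotation$start < 1 | annotation$start > annotation$end))
    stop("bad annotation intervals")
  if (nrow(table) == 0) return(table)
  rec_start <- table$position
  rec_end <- table$position + table$size - 1L
  table$gene <- vapply(seq_len(nrow(table)), function(i) {
    hit <- annotation$gene[annotation$start <= rec_end[i] &
                           annotation$end >= rec_start[i]]
    if (length(hit)) paste(unique(hit), collapse = ",") else NA_character_
  }, character(1))
  rebuild_table(table, table)
}

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 is parsed with \pkg{ape} and filtered to `gene` features (falling
#' back to all features when none are typed `gene`); gene names are taken
#' from the `Name=`, `gene=` or `ID=` attribute, in that order. BED input
#' (0-based half-open) is converted to the 1-based inclusive convention
#' used throughout.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return data.frame with `gene`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    g <- ape::read.gff(path)
    if (any(g$type == "gene")) g <- g[g$type == "gene", ]
    name <- function(attr) {
      for (key in c("Name=", "gene=", "ID=")) {
        m <- regmatches(attr, regexpr(paste0(key, "[^;]+"), attr))
        if (length(m) && nzchar(m)) return(sub(key, "", m))
      }
      NA_character_
    }
    data.frame(gene = vapply(as.character(g$attributes), name, character(1),
                             USE.NAMES = FALSE),
               start = g$start, end = g$end, stringsAsFactors = FALSE)
  } else {
    b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(gene = if (ncol(b) >= 4) b[[4]] else
                 paste0("region_", seq_len(nrow(b))),
               start = b[[2]] + 1L, end = b[[3]], stringsAsFactors = FALSE)
  }
}
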