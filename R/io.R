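# Readers and writers for the tabular formats used along the pipeline:
# SEG segment tables, MAF-like mutation tables, GCT 1.2 / plain TSV matrices,
# GMT gene sets, survival tables and kinase-substrate relation tables.
# All files are tab-separated text; coordinates are 1-based inclusive.

#' Read / write a SEG copy-number segment table
#'
#' SEG columns: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean` (log2 copy ratio). Coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return A data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `num_mark`, `log2ratio`.
#' @export
read_seg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(d)))
    stopf("SEG file %s lacks columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  data.frame(sample = as.character(d$ID), chrom = as.character(d$chrom),
             start = as.integer(d$loc.start), end = as.integer(d$loc.end),
             num_mark = as.integer(d$num.mark), log2ratio = as.numeric(d$seg.mean),
             stringsAsFactors = FALSE)
}

#' @rdname read_seg
#' @param segments Segment data.frame as returned by [read_seg()].
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(ID = segments$sample, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$num_mark %||% 1L,
                    seg.mean = segments$log2ratio, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a MAF-like somatic mutation table
#'
#' Required columns: `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`, `Variant_Type`, `Context` (the ref-centred
#' trinucleotide, e.g. `ACA`; may be `NA` for indels).
#'
#' @param path File path.
#' @return A data.frame with the columns above.
#' @export
read_maf <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Classification", "Variant_Type", "Context")
  if (!all(need %in% names(d)))
    stopf("mutation table %s lacks columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  d$Start_Position <- as.integer(d$Start_Position)
  d$Context[d$Context == "NA" | d$Context == ""] <- NA_character_
  d[, need]
}

#' @rdname read_maf
#' @param mutations Mutation data.frame.
#' @export
write_maf <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write an abundance matrix in GCT 1.2 format
#'
#' GCT 1.2: a `#1.2` version line, a dimension line, then a header with
#' `Name`, `Description` and one column per sample.
#'
#' @param path File path.
#' @param layer Layer tag for the returned [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_gct <- function(path, layer = "protein") {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "#1.2")) stopf("%s is not a GCT 1.2 file", path)
  d <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$Name
  omics_matrix(m, layer = layer)
}

#' @rdname read_gct
#' @param x Matrix (features x samples) with dimnames.
#' @export
write_gct <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  d <- data.frame(Name = rownames(x), Description = rownames(x),
                  as.data.frame(unclass(x)[, , drop = FALSE]),
                  check.names = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a plain TSV matrix (features in rows, first column = id)
#' @param path File path.
#' @param layer Layer tag for the returned [omics_matrix()].
#' @export
read_matrix_tsv <- function(path, layer = "protein") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  omics_matrix(m, layer = layer)
}

#' @rdname read_matrix_tsv
#' @param x Matrix with dimnames.
#' @param id_name Name for the feature-id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "feature") {
  d <- data.frame(rownames(x), as.data.frame(unclass(x)), check.names = FALSE)
  names(d)[1L] <- id_name
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a survival table
#'
#' Columns: `sample`, `os_time` (months), `os_event` (0/1) plus any
#' covariate or label columns.
#'
#' @param path File path.
#' @export
read_survival_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "os_time", "os_event")
  if (!all(need %in% names(d)))
    stopf("survival table %s lacks columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  if (any(d$os_time <= 0)) stopf("survival times must be positive")
  if (!all(d$os_event %in% c(0, 1))) stopf("os_event must be 0/1")
  d
}

#' @rdname read_survival_tsv
#' @param survival Survival data.frame.
#' @export
write_survival_tsv <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase-substrate relation table
#'
#' Columns: `kinase`, `substrate`, `site`, optional `source` and `score`.
#' NetworKIN-style rows (source `"networkin"`) are kept only when their score
#' exceeds `networkin_cutoff`; duplicated kinase-site pairs are dropped.
#'
#' @param path File path.
#' @param networkin_cutoff Minimum score for NetworKIN-style rows.
#' @return A data.frame with `kinase`, `substrate`, `site` and the site id
#'   `substrate_site` (`PROT_S123` style).
#' @export
read_kinase_substrate <- function(path, networkin_cutoff = 1) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("kinase", "substrate", "site")
  if (!all(need %in% names(d)))
    stopf("kinase-substrate table %s lacks columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  if (!is.null(d$source) && !is.null(d$score)) {
    keep <- d$source != "networkin" | (!is.na(d$score) & d$score > networkin_cutoff)
    d <- d[keep, , drop = FALSE]
  }
  d$substrate_site <- paste(d$substrate, d$site, sep = "_")
  d[!duplicated(paste(d$kinase, d$substrate_site)), , drop = FALSE]
}
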