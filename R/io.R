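#' Read and write accession-by-gene measurement matrices
#'
#' Measurement tables (RD copy-number estimates, raw MLPA peak intensities,
#' ddPCR concentrations) are TSV matrices: header row of gene identifiers,
#' first column of accession identifiers, empty cells for missing
#' measurements. Values must be non-negative; 0 is a meaningful copy number,
#' so missingness is encoded only by empty cells, never by sentinel values.
#'
#' @param path File path.
#' @return `read_measurements()` returns a wide tibble whose first column is
#'   `accession`; remaining columns are numeric, one per gene.
#' @export
read_measurements <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, comment = "#")
  if (names(x)[1] != "accession") {
    abort(sprintf("%s: first column must be 'accession'", path))
  }
  if (anyDuplicated(x$accession)) {
    abort(sprintf("%s: duplicated accession ids", path))
  }
  if (anyDuplicated(names(x))) {
    abort(sprintf("%s: duplicated gene ids in header", path))
  }
  vals <- as.matrix(x[-1])
  if (any(vals < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative measurement values", path))
  }
  x
}

#' @rdname read_measurements
#' @param x Wide measurement tibble (first column `accession`).
#' @param header Optional comment lines (e.g. the generating seed) written
#'   before the table, prefixed with `#`.
#' @export
write_measurements <- function(x, path, header = NULL) {
  stopifnot(names(x)[1] == "accession")
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged. Only the first three columns plus an
#' optional name column are used.
#'
#' @param path File path.
#' @return An interval tibble (`chrom`, `start`, `end`, and `name` when
#'   present).
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "#"
  )
  if (ncol(x) < 3) abort(sprintf("%s: BED needs >= 3 columns", path))
  out <- tibble(
    chrom = x[[1]],
    start = suppressWarnings(as.numeric(x[[2]])),
    end = suppressWarnings(as.numeric(x[[3]]))
  )
  if (ncol(x) >= 4) out$name <- x[[4]]
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    abort(sprintf("%s: non-numeric coordinates at line %d", path, bad))
  }
  validate_intervals(out, context = path)
  out
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed")
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  readr::write_tsv(
    dplyr::mutate(x[cols], start = format(.data$start, scientific = FALSE, trim = TRUE),
                  end = format(.data$end, scientific = FALSE, trim = TRUE)),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read and write gene models as GFF3
#'
#' GFF3 is 1-based inclusive; the reader subtracts 1 from starts and the
#' writer adds it back, so the shift is applied exactly once in each
#' direction. Genes are `gene` features carrying `ID`, `category`, `cluster`
#' and `role` attributes; exons are `exon` features with a `Parent`
#' attribute.
#'
#' @param path File path.
#' @return A gene tibble in the [mgc_annotation()] layout.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  # GRanges start is 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1
  df$end0 <- df$end
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) abort(sprintf("%s: no gene features", path))
  parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  out <- tibble(
    gene_id = genes$ID,
    chrom = as.character(genes$seqnames),
    start = genes$start0,
    end = genes$end0,
    strand = as.character(genes$strand),
    category = if ("category" %in% names(genes)) genes$category else "other",
    cluster = if ("cluster" %in% names(genes)) genes$cluster else NA_character_,
    role = if ("role" %in% names(genes)) genes$role else "member"
  )
  out$exons <- purrr::map(out$gene_id, function(id) {
    ex <- exons[parent == id, , drop = FALSE]
    ex <- ex[order(ex$start0), , drop = FALSE]
    tibble(chrom = as.character(ex$seqnames), start = ex$start0, end = ex$end0)
  })
  validate_intervals(out, context = path)
  out
}

#' @rdname read_gene_models
#' @param genes Gene tibble with an `exons` list-column.
#' @export
write_gene_models <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("write_gene_models() requires the rtracklayer package")
  }
  validate_intervals(genes, "write_gene_models")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand,
    type = "gene",
    ID = genes$gene_id,
    category = genes$category,
    cluster = genes$cluster,
    role = genes$role
  )
  ex <- tidyr::unnest(genes[, c("gene_id", "strand", "exons")], "exons")
  exon_gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
    strand = ex$strand,
    type = "exon",
    Parent = ex$gene_id
  )
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read and write structural-variant call tables
#'
#' The dialect is the BreakDancer-style TSV with columns `chrom`, `pos1`,
#' `chrom2`, `pos2`, `type`, `size`, `score`, `num_reads`, plus an optional
#' leading `accession` column for cohort-level tables. Coordinates are
#' 0-based half-open (`pos1` = start, `pos2` = end).
#'
#' @param path File path.
#' @return A call tibble: `accession` (if present), `chrom`, `start`, `end`,
#'   `sv_type`, `score`, `supporting_reads`.
#' @export
read_sv_calls <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, comment = "#")
  need <- c("chrom", "pos1", "chrom2", "pos2", "type", "size", "score", "num_reads")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: malformed SV header, missing %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    chrom = x$chrom,
    start = as.numeric(x$pos1),
    end = as.numeric(x$pos2),
    sv_type = x$type,
    score = as.numeric(x$score),
    supporting_reads = as.numeric(x$num_reads)
  )
  if ("accession" %in% names(x)) out <- dplyr::bind_cols(tibble(accession = x$accession), out)
  if (any(x$chrom != x$chrom2)) {
    abort(sprintf("%s: interchromosomal record(s); only intrachromosomal SVs supported", path))
  }
  validate_intervals(out, context = path)
  if (any(out$score < 0) || any(out$supporting_reads < 1)) {
    abort(sprintf("%s: invalid score or supporting-read count", path))
  }
  out
}

#' @rdname read_sv_calls
#' @param calls SV call tibble.
#' @export
write_sv_calls <- function(calls, path) {
  validate_intervals(calls, "write_sv_calls")
  out <- tibble(
    chrom = calls$chrom,
    pos1 = calls$start,
    chrom2 = calls$chrom,
    pos2 = calls$end,
    type = calls$sv_type,
    size = calls$end - calls$start,
    score = calls$score,
    num_reads = calls$supporting_reads
  )
  if ("accession" %in% names(calls)) {
    out <- dplyr::bind_cols(tibble(accession = calls$accession), out)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write per-accession SNP genotypes as VCF
#'
#' The reader accepts any VCF 4.x with GT fields (via the vcfR package) and
#' returns a long tibble of genotype calls; positions are converted to the
#' internal 0-based convention. The writer emits a minimal plain-text VCF 4.2
#' with GT-only FORMAT, which round-trips through the reader.
#'
#' @param path File path.
#' @return A long tibble: `chrom`, `pos` (0-based), `ref`, `alt`, `accession`,
#'   `gt` (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`, or phased equivalents).
#' @export
read_snp_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_snp_genotypes() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos1 <- as.numeric(fix$POS)
  if (anyNA(pos1)) abort(sprintf("%s: non-numeric POS", path))
  sites <- tibble(
    chrom = fix$CHROM,
    pos = pos1 - 1,
    ref = fix$REF,
    alt = fix$ALT,
    site = seq_len(nrow(fix))
  )
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(sites, as_tibble(gt)),
    cols = -c("chrom", "pos", "ref", "alt", "site"),
    names_to = "accession", values_to = "gt"
  )
  long$gt[is.na(long$gt)] <- "./."
  dplyr::select(long, "chrom", "pos", "ref", "alt", "accession", "gt")
}

#' @rdname read_snp_genotypes
#' @param snps Long SNP tibble as returned by `read_snp_genotypes()`.
#' @param header Optional extra `##` header lines (e.g. the generating seed).
#' @export
write_snp_genotypes <- function(snps, path, header = NULL) {
  wide <- tidyr::pivot_wider(
    snps,
    id_cols = c("chrom", "pos", "ref", "alt"),
    names_from = "accession", values_from = "gt", values_fill = "./."
  )
  wide <- dplyr::arrange(wide, .data$chrom, .data$pos)
  accs <- setdiff(names(wide), c("chrom", "pos", "ref", "alt"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(header)) paste0("##", header),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accs), collapse = "\t")
  )
  body <- paste(
    wide$chrom, format(wide$pos + 1, scientific = FALSE, trim = TRUE), ".",
    wide$ref, wide$alt, ".", "PASS", ".", "GT",
    do.call(paste, c(as.list(wide[accs]), sep = "\t")),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write genotype-status matrices
#'
#' Status matrices are TSV with a header row of gene identifiers and a first
#' column of accession identifiers; cells hold `REF`, `LOSS`, `GAIN`,
#' `CONFLICT`, or `NA` for missing.
#'
#' @param path File path.
#' @return A long tibble: `accession`, `gene`, `status`.
#' @export
read_genotype_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, comment = "#", na = "NA")
  if (names(x)[1] != "accession") {
    abort(sprintf("%s: first column must be 'accession'", path))
  }
  long <- tidyr::pivot_longer(x, -"accession", names_to = "gene", values_to = "status")
  bad <- setdiff(unique(long$status[!is.na(long$status)]), .statuses)
  if (length(bad) > 0) {
    abort(sprintf("%s: unknown status value(s): %s", path, paste(bad, collapse = ", ")))
  }
  long
}

#' @rdname read_genotype_matrix
#' @param calls Long genotype tibble (`accession`, `gene`, `status`).
#' @param header Optional comment line(s) written before the table.
#' @export
write_genotype_matrix <- function(calls, path, header = NULL) {
  wide <- tidyr::pivot_wider(
    calls[, c("accession", "gene", "status")],
    names_from = "gene", values_from = "status"
  )
  write_measurements_chr(wide, path, header)
}

# shared writer for character matrices with optional comment header
write_measurements_chr <- function(x, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Phenotype/climate tables are TSV with accessions in rows (first column
#' `accession`) and one numeric column per variable.
#'
#' @param path File path.
#' @return A wide tibble, first column `accession`.
#' @export
read_phenotypes <- function(path) {
  # unlike measurement matrices, phenotype values may legitimately be negative
  x <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, comment = "#")
  if (names(x)[1] != "accession") {
    abort(sprintf("%s: first column must be 'accession'", path))
  }
  x
}

#' @rdname read_phenotypes
#' @param x Wide phenotype tibble.
#' @param header Optional comment line(s).
#' @export
write_phenotypes <- function(x, path, header = NULL) write_measurements(x, path, header)
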