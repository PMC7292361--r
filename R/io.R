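#' Read a fragment file into a fragment matrix
#'
#' Parses the whitespace-delimited fragment format used by graph-cut
#' phasing tools: each line is
#' `n_pieces read_id start_1 alleles_1 [start_2 alleles_2 ...] quality`,
#' where `start` is a 1-based SNP index and `alleles` is a string over
#' `{0, 1}` — `0` is the reference allele (code `+1`), `1` the alternative
#' (code `-1`). Quality strings are parsed for shape but ignored (the MEC
#' objective here is unweighted). Reads with fewer than two alleles in
#' total are dropped with a message.
#'
#' @param path file path.
#' @param n_snps total number of SNP columns; defaults to the largest index
#'   seen in the file.
#' @return a [fragment_matrix()].
#' @export
read_fragment_file <- function(path, n_snps = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rr <- integer(0); cc <- integer(0); aa <- integer(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    np <- suppressWarnings(as.integer(tok[1]))
    if (is.na(np) || length(tok) != 2L + 2L * np + 1L)
      stop("malformed fragment record at line ", i)
    alleles_total <- 0L
    for (p in seq_len(np)) {
      start <- suppressWarnings(as.integer(tok[1L + 2L * p]))
      s <- tok[2L + 2L * p]
      ch <- strsplit(s, "")[[1]]
      if (is.na(start) || start < 1L || !all(ch %in% c("0", "1")))
        stop("invalid piece (start or allele characters) at line ", i)
      cols <- start + seq_along(ch) - 1L
      rr <- c(rr, rep.int(i, length(ch)))
      cc <- c(cc, cols)
      aa <- c(aa, ifelse(ch == "0", 1L, -1L))
      alleles_total <- alleles_total + length(ch)
    }
    if (nchar(tok[length(tok)]) != alleles_total)
      stop("quality string length mismatch at line ", i)
  }
  fragment_matrix(read = rr, col = cc, allele = aa, n_snps = n_snps)
}

#' Write a fragment matrix to a fragment file
#'
#' Inverse of [read_fragment_file()]: contiguous runs of observed columns in
#' each read become pieces; a constant placeholder quality character is
#' emitted per allele (qualities carry no information in unweighted MEC).
#'
#' @param x a [fragment_matrix()].
#' @param path output path.
#' @param read_ids optional character ids (default `read_1 ...`).
#' @return `path`, invisibly.
#' @export
write_fragment_file <- function(x, path, read_ids = NULL) {
  if (is.null(read_ids)) read_ids <- paste0("read_", seq_len(x$n_reads))
  o <- order(x$read, x$col)
  rd <- x$read[o]; cl <- x$col[o]; al <- x$allele[o]
  lines <- vapply(seq_len(x$n_reads), function(i) {
    idx <- which(rd == i)
    cols <- cl[idx]; als <- al[idx]
    brk <- c(0L, which(diff(cols) != 1L), length(cols))
    pieces <- character(0)
    n_al <- 0L
    for (p in seq_len(length(brk) - 1L)) {
      sel <- (brk[p] + 1L):brk[p + 1L]
      pieces <- c(pieces, as.character(cols[sel][1L]),
                  paste(ifelse(als[sel] == 1L, "0", "1"), collapse = ""))
      n_al <- n_al + length(sel)
    }
    paste(c((length(brk) - 1L), read_ids[i], pieces,
            strrep("#", n_al)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth diplotype as a minimal phased VCF
#'
#' Emits a VCF 4.2 subset: `##fileformat` header, the standard column
#' header with one sample, and one bi-allelic SNP record per site with a
#' phased genotype — `0|1` where haplotype 1 carries the reference allele
#' (sign `+1`), `1|0` where it carries the alternative (sign `-1`).
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @param chrom chromosome name (default `"chr1"`).
#' @param sample sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(truth, path, chrom = "chr1", sample = "SAMPLE") {
  stopifnot(inherits(truth, "sim_truth"))
  s <- truth$sites
  gt <- ifelse(truth$h_ex == 1L, "0|1", "1|0")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ",length=",
           format(truth$genome_length, scientific = FALSE), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    paste(chrom, s$pos, paste0("snp_", seq_len(nrow(s))), s$ref, s$alt,
          ".", "PASS", ".", "GT", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal phased VCF back into a truth object
#'
#' Accepts only bi-allelic SNP records: a record with a multi-base REF or
#' ALT (an indel) or a comma-separated ALT (multi-allelic) is rejected, as
#' the fragment-matrix model is defined for bi-allelic SNPs only. The first
#' sample's phased GT (`0|1` / `1|0`) becomes the haplotype sign.
#'
#' @param path VCF path.
#' @return a `sim_truth`.
#' @export
read_vcf_lite <- function(path) {
  lines <- readLines(path)
  glen <- NA_real_
  ctg <- grep("^##contig=", lines, value = TRUE)
  if (length(ctg)) {
    m <- regmatches(ctg[1], regexec("length=([0-9]+)", ctg[1]))[[1]]
    if (length(m) == 2L) glen <- as.numeric(m[2])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no variant records in ", path)
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 10L)) stop("VCF record with no sample column")
  pos <- as.integer(vapply(f, `[[`, "", 2L))
  ref <- vapply(f, `[[`, "", 4L)
  alt <- vapply(f, `[[`, "", 5L)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic ALT rejected: only bi-allelic SNPs are supported")
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("indel record rejected: only bi-allelic SNPs are supported")
  gt <- substr(vapply(f, `[[`, "", 10L), 1L, 3L)
  if (!all(gt %in% c("0|1", "1|0")))
    stop("every record needs a phased heterozygous GT (0|1 or 1|0)")
  h <- ifelse(gt == "0|1", 1L, -1L)
  if (is.na(glen)) glen <- max(pos)
  diplotype_from_sites(pos, ref, alt, h, genome_length = glen)
}

#' Write phased blocks in a HapCUT-like text format
#'
#' One `BLOCK:` header per phased block (`offset`, `len` in SNPs), then one
#' line per phased SNP — index, haplotype-1 allele, haplotype-2 allele (0 =
#' reference, 1 = alternative) — and a `********` terminator.
#'
#' @param result a `hap_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_blocks <- function(result, path) {
  td <- tidy(result)
  td <- td[td$phased & !is.na(td$sign), ]
  out <- character(0)
  for (b in unique(td$block)) {
    rows <- td[td$block == b, ]
    out <- c(out,
             paste0("BLOCK: offset: ", rows$col[1L], " len: ", nrow(rows)),
             paste(rows$col, ifelse(rows$sign == 1L, 0L, 1L),
                   ifelse(rows$sign == 1L, 1L, 0L), sep = "\t"),
             "********")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read phased blocks written by [write_phased_blocks()]
#'
#' @param path file path.
#' @param n_snps total number of SNP columns (default: largest index seen).
#' @return a list shaped like a `hap_assembly` (haplotype + blocks tibble);
#'   usable directly with [switch_error()].
#' @export
read_phased_blocks <- function(path, n_snps = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  col <- integer(0); sign <- integer(0); block <- integer(0)
  b <- 0L
  for (ln in lines) {
    if (startsWith(ln, "BLOCK")) { b <- b + 1L; next }
    if (startsWith(ln, "****")) next
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    col <- c(col, as.integer(tok[1]))
    sign <- c(sign, if (tok[2] == "0") 1L else -1L)
    block <- c(block, b)
  }
  if (is.null(n_snps)) n_snps <- max(col)
  h <- rep(NA_integer_, n_snps)
  h[col] <- sign
  blk <- rep(NA_integer_, n_snps)
  blk[col] <- block
  # unphased columns become singleton pseudo-blocks after the real ones
  blk[is.na(blk)] <- b + seq_len(sum(is.na(blk)))
  structure(list(haplotype = h,
                 blocks = tibble::tibble(col = seq_len(n_snps),
                                         block = blk,
                                         phased = !is.na(h))),
            class = "hap_assembly_file")
}
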