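#' Read biallelic SNV genotypes from a VCF
#'
#' Reads a VCF 4.x file and returns one row per sample per biallelic SNV
#' allele. Multiallelic records are split into one row per alternative
#' allele; genotypes are re-expressed relative to that allele (`hom_ref`,
#' `het`, `hom_alt`, or `missing` for `./.`). Non-SNV alleles (indels,
#' symbolic alleles) are skipped and their count reported with a message.
#' Positions stay 1-based.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `genotype`.
#' @export
read_vcf_sites <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample = character(), genotype = character()
  )
  if (nrow(v@fix) == 0L) {
    return(empty)
  }
  if (ncol(v@gt) < 2L) {
    abort("VCF has no sample genotype columns")
  }
  fmt <- v@gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(x) "GT" %in% x, logical(1)))) {
    abort("VCF records lack the GT format field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  fix <- v@fix

  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt[r, ]
    codes <- strsplit(gts, "[/|]")
    keep <- list()
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L ||
          !toupper(alt) %in% c("A", "C", "G", "T") ||
          !toupper(ref) %in% c("A", "C", "G", "T")) {
        n_skipped <- n_skipped + 1L
        next
      }
      genotype <- unname(vapply(codes, function(cd) {
        if (length(cd) == 0L || anyNA(cd) || any(cd == ".")) return("missing")
        n_alt <- sum(cd == as.character(k))
        c("hom_ref", "het", "hom_alt")[min(n_alt, 2L) + 1L]
      }, character(1)))
      keep[[length(keep) + 1L]] <- tibble(
        chrom = fix[r, "CHROM"],
        pos = as.integer(fix[r, "POS"]),
        ref = toupper(ref),
        alt = toupper(alt),
        sample = samples,
        genotype = genotype
      )
    }
    if (length(keep) > 0L) rows[[r]] <- dplyr::bind_rows(keep)
  }
  if (n_skipped > 0L) {
    inform(paste0("skipped ", n_skipped, " non-SNV allele(s)"))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

#' Annotate a VCF with ABB scores
#'
#' Streams a VCF text file, appends an `ABB=<score>` INFO entry to every
#' record whose (chrom, pos) appears in the score table, and writes the
#' result. An `##INFO` header line describing the key is inserted. Records
#' without a score are passed through unchanged.
#'
#' @param vcf_in Path to the input VCF (plain text).
#' @param score_table Tibble with at least `chrom`, `pos`, `abb` columns.
#' @param vcf_out Path for the annotated VCF.
#'
#' @return Invisibly, the number of annotated records.
#' @export
annotate_vcf <- function(vcf_in, score_table, vcf_out) {
  lines <- readLines(vcf_in)
  is_header <- startsWith(lines, "#")
  info_line <- paste0(
    '##INFO=<ID=ABB,Number=1,Type=Float,Description=',
    '"ABB genotype callability score (precision of the systematic-error ',
    'classifier); higher means less callable">'
  )
  hdr <- lines[is_header]
  chrom_hdr <- startsWith(hdr, "#CHROM")
  if (any(chrom_hdr)) {
    at <- which(chrom_hdr)[1]
    hdr <- append(hdr, info_line, after = at - 1L)
  } else {
    hdr <- c(hdr, info_line)
  }
  body <- lines[!is_header]
  n_annot <- 0L
  if (length(body) > 0L) {
    key <- paste(score_table$chrom, score_table$pos, sep = ":")
    abb <- setNames(score_table$abb, key)
    parts <- strsplit(body, "\t", fixed = TRUE)
    body <- vapply(parts, function(f) {
      if (length(f) < 8L) return(paste(f, collapse = "\t"))
      k <- paste(f[1], f[2], sep = ":")
      score <- abb[k]
      if (!is.na(score)) {
        tag <- sprintf("ABB=%.6f", score)
        f[8] <- if (f[8] %in% c(".", "")) tag else paste0(f[8], ";", tag)
        n_annot <<- n_annot + 1L
      }
      paste(f, collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), vcf_out)
  invisible(n_annot)
}
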