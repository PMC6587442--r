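#' Parse one samtools mpileup record
#'
#' Decodes a single line of 6-column mpileup text (chrom, pos, ref, depth,
#' bases, base qualities) into per-position read evidence. Reads whose base
#' quality (Phred+33) falls below `min_baseq` are excluded from both the
#' informative depth and the alternative count. Pileup markup is consumed
#' according to the mpileup grammar: `^` plus the following mapping-quality
#' byte, `$`, indel spans (`+N...`/`-N...`) and deletion/skip placeholders
#' (`*`, `#`, `<`, `>`) never count as base calls. `.` and `,` count as the
#' reference allele; base letters are pooled across strands
#' (case-insensitive). The alternative allele is the single most frequent
#' non-reference base among quality-passing reads, ties broken
#' alphabetically; `N` calls contribute to depth but are never the
#' alternative allele.
#'
#' @param line Character scalar, one mpileup record.
#' @param min_baseq Minimum base quality (Phred scale) for a read to count
#'   as informative. Default 20, the conventional informativeness cutoff.
#' @param .line_number Optional line number used in parse error messages.
#'
#' @return A one-row tibble with columns `chrom`, `pos`, `ref_base`,
#'   `depth_informative`, `alt_count` and `ab` (`alt_count /
#'   depth_informative`, `NA` when no read passes the filter).
#'
#' @examples
#' parse_pileup_line("chr1\t100\tA\t5\t..,..\tIIIII")
#' parse_pileup_line("chr1\t100\tA\t6\t.+2AT,GGg.\tIIIIII", min_baseq = 0)
#' @export
parse_pileup_line <- function(line, min_baseq = 20, .line_number = NA_integer_) {
  where <- if (is.na(.line_number)) "" else paste0(" at line ", .line_number)
  fields <- strsplit(trimws(line, which = "right"), "\t", fixed = TRUE)[[1]]
  if (length(fields) == 1L) {
    # tolerate space-separated test strings
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  }
  if (length(fields) != 6L) {
    abort(paste0("pileup parse error", where, ": expected 6 columns, got ",
                 length(fields)))
  }
  chrom <- fields[1]
  pos <- suppressWarnings(as.integer(fields[2]))
  if (is.na(pos) || pos < 1L) {
    abort(paste0("pileup parse error", where, ": invalid position '",
                 fields[2], "'"))
  }
  ref <- toupper(fields[3])
  bases <- fields[5]
  quals <- fields[6]
  qv <- utf8ToInt(quals) - 33L
  nq <- length(qv)

  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  obs <- character(nq)
  i <- 1L
  j <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) {
        abort(paste0("pileup parse error", where, ": dangling '^'"))
      }
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      k <- i + 1L
      num <- ""
      while (k <= n && grepl("^[0-9]$", chars[k])) {
        num <- paste0(num, chars[k])
        k <- k + 1L
      }
      if (num == "") {
        abort(paste0("pileup parse error", where,
                     ": indel marker without length"))
      }
      span <- as.integer(num)
      if (k + span - 1L > n) {
        abort(paste0("pileup parse error", where, ": truncated indel span"))
      }
      i <- k + span
    } else {
      j <- j + 1L
      if (j > nq) {
        abort(paste0("pileup parse error", where,
                     ": more base calls than quality characters"))
      }
      obs[j] <- ch
      i <- i + 1L
    }
  }
  if (j != nq) {
    abort(paste0("pileup parse error", where, ": ", j,
                 " base calls but ", nq, " quality characters"))
  }

  is_ref <- obs %in% c(".", ",")
  base_up <- toupper(obs)
  is_base <- base_up %in% c("A", "C", "G", "T", "N")
  pass <- qv >= min_baseq
  counted <- pass & (is_ref | is_base)
  depth_informative <- sum(counted)

  alt_candidates <- base_up[counted & is_base & base_up != "N" & base_up != ref]
  if (length(alt_candidates) > 0L) {
    tab <- table(alt_candidates)
    # ties: table() is alphabetical, which.max takes the first
    alt_count <- as.integer(tab[which.max(tab)])
  } else {
    alt_count <- 0L
  }

  tibble(
    chrom = chrom,
    pos = pos,
    ref_base = ref,
    depth_informative = depth_informative,
    alt_count = alt_count,
    ab = if (depth_informative > 0L) alt_count / depth_informative else NA_real_
  )
}

#' Read an mpileup text file into a site observation table
#'
#' Applies [parse_pileup_line()] to every record of a samtools mpileup
#' 6-column text file.
#'
#' @param path Path to the pileup text file.
#' @param min_baseq Minimum base quality; see [parse_pileup_line()].
#' @param sample Optional sample identifier added as a `sample` column.
#'
#' @return A tibble of site observations, one row per pileup record.
#' @export
read_pileup <- function(path, min_baseq = 20, sample = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- purrr::imap(lines, function(l, i) {
    parse_pileup_line(l, min_baseq = min_baseq, .line_number = i)
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(sample)) {
    out <- dplyr::mutate(out, sample = sample, .before = 1L)
  }
  out
}
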