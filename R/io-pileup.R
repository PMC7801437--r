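# Per-cell pileups are data.frames with one row per covered position:
#   cell, pos (1-based), ref, depth,
#   fwd_A..fwd_T, rev_A..rev_T   strand-resolved base counts,
#   end_A..end_T                 reads supporting the base that terminate
#                                at this position (both strands),
#   skipped                      reads counted in depth but not as a base
#                                (N/n, deletion '*', reference skips).

PILEUP_BASES <- c("A", "C", "G", "T")
pileup_count_cols <- function() {
  c(paste0("fwd_", PILEUP_BASES), paste0("rev_", PILEUP_BASES),
    paste0("end_", PILEUP_BASES), "skipped")
}

count_char <- function(s, ch) nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))

# Remove indel specifications ("+2AT" / "-3ACG") from base strings.
# Indels attach to the preceding read base and are not substitutions.
strip_indels <- function(s) {
  has <- grepl("[+-][0-9]", s)
  for (i in which(has)) {
    x <- s[i]
    repeat {
      m <- regexpr("[+-][0-9]+", x)
      if (m == -1L) break
      n <- as.integer(substr(x, m + 1L, m + attr(m, "match.length") - 1L))
      x <- paste0(substr(x, 1L, m - 1L),
                  substring(x, m + attr(m, "match.length") + n))
    }
    s[i] <- x
  }
  s
}

# Decode mpileup base strings into strand-resolved counts.
# Returns a matrix with pileup_count_cols() columns, one row per string.
decode_pileup_bases <- function(bases, ref, depth, where = "pileup") {
  ref <- toupper(ref)
  s <- gsub("\\^.", "", bases)     # read starts: '^' + mapping quality
  s <- strip_indels(s)
  syms <- c(".", ",", "A", "C", "G", "T", "a", "c", "g", "t")
  ends <- sapply(syms, function(ch)
    count_char(s, paste0(ch, "$")) / 2L)
  if (length(bases) == 1L) ends <- matrix(ends, nrow = 1L,
                                          dimnames = list(NULL, syms))
  s <- gsub("$", "", s, fixed = TRUE)
  tot <- sapply(syms, function(ch) count_char(s, ch))
  if (length(bases) == 1L) tot <- matrix(tot, nrow = 1L,
                                         dimnames = list(NULL, syms))
  skipped <- count_char(s, "N") + count_char(s, "n") +
    count_char(s, "*") + count_char(s, ">") + count_char(s, "<")
  out <- matrix(0L, nrow = length(bases), ncol = 13L,
                dimnames = list(NULL, pileup_count_cols()))
  for (b in PILEUP_BASES) {
    out[, paste0("fwd_", b)] <- tot[, b]
    out[, paste0("rev_", b)] <- tot[, tolower(b)]
    out[, paste0("end_", b)] <- ends[, b] + ends[, tolower(b)]
  }
  # '.'/',' are reference matches on the forward/reverse strand
  ri <- cbind(seq_along(bases), match(paste0("fwd_", ref),
                                      colnames(out)))
  out[ri] <- out[ri] + tot[, "."]
  ri[, 2] <- match(paste0("rev_", ref), colnames(out))
  out[ri] <- out[ri] + tot[, ","]
  ri[, 2] <- match(paste0("end_", ref), colnames(out))
  out[ri] <- out[ri] + ends[, "."] + ends[, ","]
  out[, "skipped"] <- skipped
  decoded <- rowSums(out[, c(paste0("fwd_", PILEUP_BASES),
                             paste0("rev_", PILEUP_BASES)), drop = FALSE]) +
    skipped
  bad <- which(decoded != depth)
  if (length(bad))
    stop_ctx("validation error in ", where, ": declared depth ",
             depth[bad[1]], " but decoded ", decoded[bad[1]],
             " reads at record ", bad[1])
  storage.mode(out) <- "integer"
  out
}

#' Read a samtools mpileup text file for one cell
#'
#' Decodes the mpileup base-string dialect into strand-resolved per-base
#' counts: uppercase/`.` are forward-strand reads, lowercase/`,` reverse;
#' `^X`/`$` read-start/read-end marks are recorded (`$` feeds the
#' read-end counts); `+n.../−n...` indel spans and `*`, `N`, `>`, `<`
#' symbols are skipped, never counted as substitutions. A record whose
#' declared depth disagrees with the decoded read count beyond that
#' accounting is a validation error. Base qualities are parsed but not
#' used (the downstream filters are coverage/strand/position-based).
#'
#' @param path mpileup text file.
#' @param cell cell id; defaults to the file name stem.
#' @return A pileup data.frame (one row per position).
#' @export
read_pileup <- function(path, cell = NULL) {
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  cell <- cell %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_pileup(cell))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 5L))
    stop_ctx("parse error in ", path, " line ", which(nf < 5L)[1],
             ": expected >= 5 mpileup fields")
  pos <- as.integer(vapply(f, `[`, "", 2L))
  ref <- toupper(vapply(f, `[`, "", 3L))
  depth <- as.integer(vapply(f, `[`, "", 4L))
  bases <- vapply(f, function(x) if (length(x) >= 5L) x[5L] else "", "")
  if (anyNA(pos) || anyNA(depth))
    stop_ctx("parse error in ", path, ": non-numeric pos/depth field")
  counts <- decode_pileup_bases(bases, ref, depth, where = path)
  df <- data.frame(cell = cell, pos = pos, ref = ref, depth = depth,
                   counts, stringsAsFactors = FALSE)
  df[order(df$pos), , drop = FALSE]
}

empty_pileup <- function(cell) {
  df <- data.frame(cell = character(0), pos = integer(0),
                   ref = character(0), depth = integer(0))
  for (cl in pileup_count_cols()) df[[cl]] <- integer(0)
  df
}

#' Read a directory of per-cell pileup files
#'
#' Cell ids default to file name stems; a two-column TSV `manifest`
#' (`file`, `cell`, with header) overrides them.
#'
#' @param dir directory containing `*.pileup` / `*.txt` files.
#' @param manifest optional manifest TSV path.
#' @return Named list of pileup data.frames, one per cell.
#' @export
read_pileup_dir <- function(dir, manifest = NULL) {
  if (!is.null(manifest)) {
    man <- read.table(manifest, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    files <- file.path(dir, man$file)
    cells <- man$cell
  } else {
    files <- list.files(dir, pattern = "\\.(pileup|txt)$", full.names = TRUE)
    cells <- sub("\\.[^.]*$", "", basename(files))
  }
  if (!length(files)) stop_ctx("no pileup files found in ", dir)
  setNames(Map(read_pileup, files, cells), cells)
}

#' Write a pileup data.frame as samtools mpileup text
#'
#' Inverse of [read_pileup()] up to read ordering inside the base string
#' (strand totals, read-end totals and skipped counts round-trip).
#'
#' @param p pileup data.frame.
#' @param path output path.
#' @param chrom chromosome name (default `"MT"`).
#' @return `path`, invisibly.
#' @export
write_pileup <- function(p, path, chrom = "MT") {
  enc_one <- function(row) {
    parts <- character(0)
    for (b in PILEUP_BASES) {
      fwd <- row[[paste0("fwd_", b)]]
      rev <- row[[paste0("rev_", b)]]
      nend <- row[[paste0("end_", b)]]
      ef <- min(nend, fwd); er <- nend - ef
      is_ref <- b == row$ref
      up <- if (is_ref) "." else b
      lo <- if (is_ref) "," else tolower(b)
      parts <- c(parts,
                 strrep(up, fwd - ef), strrep(paste0(up, "$"), ef),
                 strrep(lo, rev - er), strrep(paste0(lo, "$"), er))
    }
    paste0(paste(parts, collapse = ""), strrep("N", row$skipped))
  }
  bases <- vapply(seq_len(nrow(p)), function(i) enc_one(p[i, ]), "")
  quals <- strrep("I", p$depth)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%s\t%s", chrom, p$pos, p$ref,
                     p$depth, bases, quals), path)
  invisible(path)
}
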