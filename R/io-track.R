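#' Construct a per-base conservation track
#'
#' Holds one conservation score in \[0, 1\] (e.g. 100-way phastCons) per
#' 1-based mtDNA position. Positions must be strictly increasing.
#'
#' @param positions integer vector of 1-based positions.
#' @param score numeric vector of the same length, all in \[0, 1\].
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(positions, score) {
  positions <- as.integer(positions)
  if (length(positions) != length(score))
    stop_ctx("positions and score lengths differ")
  if (any(diff(positions) <= 0))
    stop_ctx("validation error: positions must be strictly increasing")
  if (any(positions < 1)) stop_ctx("positions are 1-based (>= 1)")
  if (any(is.na(score)) || any(score < 0) || any(score > 1))
    stop_ctx("validation error: scores must lie in [0, 1]")
  structure(list(positions = positions, score = as.numeric(score)),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("conservation_track: %d positions [%d..%d], mean score %.3f\n",
              length(x$positions), min(x$positions), max(x$positions),
              mean(x$score)))
  invisible(x)
}

#' Look up track scores at positions
#' @param track a [conservation_track()].
#' @param positions positions to look up.
#' @return Numeric scores; errors if any position is uncovered.
#' @export
track_score_at <- function(track, positions) {
  idx <- match(as.integer(positions), track$positions)
  if (anyNA(idx))
    stop_ctx("position(s) without a conservation score: ",
             paste(head(positions[is.na(idx)], 5), collapse = ", "))
  track$score[idx]
}

#' Read a conservation track (fixedStep wiggle or bedGraph)
#'
#' bedGraph half-open 0-based intervals are expanded to per-base 1-based
#' positions; fixedStep blocks are expanded with their declared start and
#' step. Overlapping intervals or scores outside \[0, 1\] are rejected.
#'
#' @param path input file.
#' @param format `"fixedstep-wig"` or `"bedgraph"`.
#' @param mt_length optional declared mtDNA length; positions beyond it
#'   are a validation error.
#' @return A [conservation_track()].
#' @export
read_conservation_track <- function(path,
                                    format = c("fixedstep-wig", "bedgraph"),
                                    mt_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ctx("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (format == "bedgraph") {
    f <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(f) != 4))
      stop_ctx("parse error in ", path, " line ",
               which(lengths(f) != 4)[1], ": expected 4 bedGraph fields")
    start0 <- as.integer(vapply(f, `[`, "", 2))
    end0 <- as.integer(vapply(f, `[`, "", 3))
    val <- as.numeric(vapply(f, `[`, "", 4))
    if (anyNA(start0) || anyNA(end0) || anyNA(val))
      stop_ctx("parse error in ", path, ": non-numeric bedGraph field")
    pos <- unlist(Map(function(s, e) seq.int(s + 1L, e), start0, end0))
    score <- rep(val, end0 - start0)
  } else {
    pos <- integer(0); score <- numeric(0)
    cur <- NA_integer_; step <- 1L
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (startsWith(ln, "fixedStep")) {
        get_kv <- function(key, default = NA) {
          m <- regmatches(ln, regexec(paste0(key, "=([^ \t]+)"), ln))[[1]]
          if (length(m) < 2) default else m[2]
        }
        cur <- as.integer(get_kv("start"))
        step <- as.integer(get_kv("step", "1"))
        if (is.na(cur))
          stop_ctx("parse error in ", path, " line ", i,
                   ": fixedStep without start=")
      } else {
        if (is.na(cur))
          stop_ctx("parse error in ", path, " line ", i,
                   ": value before any fixedStep header")
        v <- suppressWarnings(as.numeric(ln))
        if (is.na(v))
          stop_ctx("parse error in ", path, " line ", i, ": not a number")
        pos <- c(pos, cur); score <- c(score, v)
        cur <- cur + step
      }
    }
  }
  if (anyDuplicated(pos))
    stop_ctx("validation error: overlapping intervals (position ",
             pos[anyDuplicated(pos)], " covered twice)")
  if (!is.null(mt_length) && any(pos > mt_length))
    stop_ctx("validation error: position beyond declared mtDNA length ",
             mt_length)
  o <- order(pos)
  conservation_track(pos[o], score[o])
}

#' Write a conservation track as bedGraph
#' @param track a [conservation_track()].
#' @param path output path.
#' @param chrom chromosome name to write (default `"MT"`).
#' @return `path`, invisibly.
#' @export
write_conservation_track <- function(track, path, chrom = "MT") {
  # collapse runs of consecutive positions with equal score
  p <- track$positions; s <- track$score
  brk <- c(TRUE, diff(p) != 1L | diff(s) != 0)
  grp <- cumsum(brk)
  start0 <- tapply(p, grp, min) - 1L
  end0 <- tapply(p, grp, max)
  val <- tapply(s, grp, `[`, 1)
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start0, end0,
                     format(val, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}
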