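#' Read a reference-anchored multiple alignment (MAF)
#'
#' Parses standard MAF (`a` block lines followed by `s` rows; `##maf`
#' headers and `i`/`e`/`q` annotation rows are tolerated and skipped) into a
#' list of [MafBlock-class] objects. Row sources are expected to be named
#' `species.chrom`. MAF row semantics are kept as-is: `start` is 0-based on
#' the row's own strand and `srcSize` records the full source length, so
#' negative-strand rows can be projected to forward coordinates when
#' needed.
#'
#' @param path path to a MAF file.
#' @return list of `MafBlock`; the first `s` row of each block is the
#'   reference row.
#' @export
readMaf <- function(path) {
  if (!file.exists(path)) stop("cannot read MAF file: ", path, call. = FALSE)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur$src)) {
      blk <- tryCatch(
        new("MafBlock", src = cur$src, start = cur$start, size = cur$size,
            strand = cur$strand, srcSize = cur$srcSize, text = cur$text),
        error = function(e) stop("MAF block ", length(blocks) + 1L, ": ",
                                 conditionMessage(e), call. = FALSE))
      blocks[[length(blocks) + 1L]] <- blk
    }
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list(src = character(), start = integer(), size = integer(),
                  strand = character(), srcSize = integer(), text = character())
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      if (is.null(cur)) stop("MAF 's' row outside a block", call. = FALSE)
      f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(f) != 7L) stop("malformed MAF 's' row: ", ln, call. = FALSE)
      cur$src <- c(cur$src, f[2]); cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4])); cur$strand <- c(cur$strand, f[5])
      cur$srcSize <- c(cur$srcSize, as.integer(f[6])); cur$text <- c(cur$text, f[7])
    }
    # '#', 'i', 'e', 'q' and blank lines skipped
  }
  blocks <- flush(cur, blocks)
  if (length(blocks) == 0L) stop("no alignment blocks in MAF file: ", path,
                                 call. = FALSE)
  blocks
}

#' Write MAF blocks
#'
#' @param blocks list of [MafBlock-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b@src, b@start, b@size,
                       b@strand, b@srcSize, b@text), con)
  }
  invisible(path)
}

# forward-strand reference positions (1-based) of each non-gap reference
# column; reference rows must be '+' strand
.mafRefPositions <- function(block, refRow = 1L) {
  if (block@strand[refRow] != "+")
    stop("reference row on '-' strand is not supported", call. = FALSE)
  chars <- strsplit(block@text[refRow], "")[[1L]]
  nongap <- chars != "-"
  pos <- integer(length(chars))
  pos[nongap] <- block@start[refRow] + seq_len(sum(nongap))  # 0-based start -> 1-based
  pos
}
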