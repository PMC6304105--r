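#' Build evolutionarily conserved pairs of neighboring elements
#'
#' A pair of elements is an evolutionarily conserved neighbor pair if, in
#' every provided outgroup genome, the two elements are consecutive in
#' coordinate order, on the same chromosome, and at most `maxDist` bases
#' apart (inner, end-to-start distance; overlapping elements count as
#' distance 0). Elements missing from any outgroup are excluded from
#' pairing (with a message).
#'
#' @param locations named list of `GRanges`, one per outgroup genome, each
#'   with a `name` metadata column holding element ids; every element may
#'   appear at most once per outgroup.
#' @param maxDist maximum inner distance within an outgroup (default 1 Mb).
#' @return a `data.frame` with columns `elementA`, `elementB` and one inner
#'   distance column `dist.<outgroup>` per outgroup.
#' @export
buildReferencePairs <- function(locations, maxDist = 1e6) {
  stopifnot(is.list(locations), length(locations) >= 1L,
            !is.null(names(locations)), all(nzchar(names(locations))))
  for (og in names(locations)) {
    gr <- locations[[og]]
    if (is.null(gr$name)) stop("outgroup '", og, "' lacks a name column",
                               call. = FALSE)
    if (anyDuplicated(gr$name))
      stop("element(s) appearing more than once in outgroup '", og, "'",
           call. = FALSE)
  }
  common <- Reduce(intersect, lapply(locations, function(g) g$name))
  excluded <- setdiff(unique(unlist(lapply(locations, function(g) g$name))),
                      common)
  if (length(excluded))
    message(length(excluded),
            " element(s) absent from at least one outgroup excluded from pairing")
  perOg <- lapply(names(locations), function(og) {
    gr <- locations[[og]]
    gr <- gr[gr$name %in% common]
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr))]
    n <- length(gr)
    if (n < 2L) return(NULL)
    i <- seq_len(n - 1L)
    sameChrom <- as.character(GenomicRanges::seqnames(gr))[i] ==
      as.character(GenomicRanges::seqnames(gr))[i + 1L]
    dist <- pmax(0, GenomicRanges::start(gr)[i + 1L] -
                   GenomicRanges::end(gr)[i] - 1)
    ok <- sameChrom & dist <= maxDist
    if (!any(ok)) return(NULL)
    a <- gr$name[i][ok]; b <- gr$name[i + 1L][ok]; d <- dist[ok]
    # unordered pair key
    key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
    data.frame(key = key, a = ifelse(a < b, a, b), b = ifelse(a < b, b, a),
               dist = d, stringsAsFactors = FALSE)
  })
  names(perOg) <- names(locations)
  perOg <- perOg[!vapply(perOg, is.null, TRUE)]
  if (length(perOg) < length(locations))
    return(data.frame(elementA = character(), elementB = character()))
  keys <- Reduce(intersect, lapply(perOg, `[[`, "key"))
  if (length(keys) == 0L)
    return(data.frame(elementA = character(), elementB = character()))
  first <- perOg[[1L]][match(keys, perOg[[1L]]$key), ]
  out <- data.frame(elementA = first$a, elementB = first$b,
                    stringsAsFactors = FALSE)
  for (og in names(perOg))
    out[[paste0("dist.", og)]] <-
      perOg[[og]]$dist[match(keys, perOg[[og]]$key)]
  out[order(out$elementA, out$elementB), , drop = FALSE]
}

#' Evaluate conserved-pair recovery in an assembly
#'
#' The contiguity statistic: a conserved neighbor pair is `recovered` when
#' both elements have retained hits on the same scaffold at most `maxDist`
#' bases apart (inner distance between the hit spans; overlapping hits
#' count as 0), `unmapped` when either element lacks a retained hit, and
#' `split` otherwise (different scaffolds, or same scaffold but too far).
#'
#' @param pairs output of [buildReferencePairs()].
#' @param bestHits output of [filterHits()]: one best hit per element.
#' @param maxDist maximum inner distance in the assembly (default 1 Mb).
#' @return a [ContiguityReport-class].
#' @export
evaluatePairs <- function(pairs, bestHits, maxDist = 1e6) {
  n <- nrow(pairs)
  status <- character(n); targetA <- targetB <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  ia <- match(pairs$elementA, bestHits$query_id)
  ib <- match(pairs$elementB, bestHits$query_id)
  for (k in seq_len(n)) {
    if (is.na(ia[k]) || is.na(ib[k])) { status[k] <- "unmapped"; next }
    sa <- as.character(GenomicRanges::seqnames(bestHits))[ia[k]]
    sb <- as.character(GenomicRanges::seqnames(bestHits))[ib[k]]
    targetA[k] <- sa; targetB[k] <- sb
    if (sa != sb) { status[k] <- "split"; next }
    s1 <- GenomicRanges::start(bestHits)[ia[k]]; e1 <- GenomicRanges::end(bestHits)[ia[k]]
    s2 <- GenomicRanges::start(bestHits)[ib[k]]; e2 <- GenomicRanges::end(bestHits)[ib[k]]
    d <- if (s1 <= s2) s2 - e1 - 1 else s1 - e2 - 1
    distance[k] <- max(0, d)
    status[k] <- if (distance[k] <= maxDist) "recovered" else "split"
  }
  detail <- S4Vectors::DataFrame(
    elementA = pairs$elementA, elementB = pairs$elementB,
    status = status, targetA = targetA, targetB = targetB,
    distance = distance)
  nRec <- sum(status == "recovered")
  new("ContiguityReport", nPairs = as.integer(n), nRecovered = as.integer(nRec),
      fraction = if (n > 0) nRec / n else NaN, detail = detail)
}
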