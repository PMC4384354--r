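## Secondary-structure motif classification of fragment pairs and the
## motif preference score.

MOTIF_LEVELS <- c("HH", "SS", "LL", "HL", "HS", "SL")
TYPE_LEVELS <- c("H", "S", "L")

motif_label <- function(a, b) {
  if (is.na(a) || is.na(b)) stop("missing secondary-structure type")
  if (!all(c(a, b) %in% TYPE_LEVELS))
    stop("secondary-structure types must be H, S or L")
  # unordered label, written in the conventional H < S < L order
  o <- order(match(c(a, b), TYPE_LEVELS))
  paste0(c(a, b)[o][1L], c(a, b)[o][2L])
}

#' Classify a fragment pair into one of six secondary-structure motifs
#'
#' The motif is the unordered pair of the center-residue 3-state types of
#' the two fragments: HH, SS, LL, HL, HS or SL.
#'
#' @param p a \code{fragment_pair} with \code{ss_a} and \code{ss_b} set.
#' @return Motif label (character).
#' @export
classify_pair_motif <- function(p) motif_label(p$ss_a, p$ss_b)

pair_ss_vectors <- function(pairs) {
  list(a = vapply(pairs, function(p) as.character(p$ss_a), character(1L)),
       b = vapply(pairs, function(p) as.character(p$ss_b), character(1L)))
}

#' Fragment-type probabilities at interfaces
#'
#' Each pair record contributes two fragments; the probability of a type
#' is its fragment count divided by twice the number of records.
#'
#' @param pairs non-empty list of \code{fragment_pair} with types set.
#' @return Named numeric vector of probabilities for H, S, L (sums to 1).
#' @export
fragment_type_probs <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  ss <- pair_ss_vectors(pairs)
  counts <- table(factor(c(ss$a, ss$b), levels = TYPE_LEVELS))
  setNames(as.numeric(counts) / (2 * length(pairs)), TYPE_LEVELS)
}

#' Motif counts, probabilities and preference scores
#'
#' Counts the six motifs over pair records, computes fragment-type
#' probabilities over individual fragments (two per record), and derives
#' the preference score of each motif.
#'
#' @param pairs non-empty list of \code{fragment_pair} with types set.
#' @return Object of class \code{motif_stats}: list with
#'   \code{motif_counts}, \code{motif_probs}, \code{type_probs} and
#'   \code{preference}.
#' @export
motif_stats <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  ss <- pair_ss_vectors(pairs)
  labels <- vapply(seq_along(pairs),
                   function(k) motif_label(ss$a[k], ss$b[k]), character(1L))
  motif_counts <- table(factor(labels, levels = MOTIF_LEVELS))
  stats <- structure(list(
    motif_counts = setNames(as.integer(motif_counts), MOTIF_LEVELS),
    motif_probs = setNames(as.numeric(motif_counts) / length(pairs),
                           MOTIF_LEVELS),
    type_probs = fragment_type_probs(pairs),
    preference = NULL
  ), class = "motif_stats")
  stats$preference <- preference_scores(stats)
  stats
}

#' Motif preference scores
#'
#' For motif XY the score is \code{ln(P(XY) / (P(X) P(Y)))}, including the
#' homogeneous motifs, where it is \code{ln(P(XX) / P(X)^2)}. This is the
#' printed form of the score: no combinatorial factor of 2 enters the
#' null of the heterogeneous motifs (see the methods vignette). Motifs
#' with zero observed count score \code{-Inf}.
#'
#' @param stats a \code{motif_stats} object (the \code{preference} slot
#'   may be empty).
#' @return Named numeric vector of scores for the six motifs.
#' @export
preference_scores <- function(stats) {
  tp <- stats$type_probs
  zero <- names(tp)[tp <= 0]
  if (length(zero))
    stop("fragment type(s) with zero probability: ",
         paste(zero, collapse = ", "))
  vapply(MOTIF_LEVELS, function(m) {
    x <- substr(m, 1L, 1L)
    y <- substr(m, 2L, 2L)
    p <- stats$motif_probs[[m]]
    if (p <= 0) return(-Inf)
    log(p / (tp[[x]] * tp[[y]]))
  }, numeric(1L))
}

#' @export
print.motif_stats <- function(x, ...) {
  df <- data.frame(
    motif = MOTIF_LEVELS,
    count = x$motif_counts[MOTIF_LEVELS],
    probability = round(x$motif_probs[MOTIF_LEVELS], 4),
    preference = round(x$preference[MOTIF_LEVELS], 4)
  )
  rownames(df) <- NULL
  cat("motif statistics over", sum(x$motif_counts), "pair records\n")
  cat("type probabilities:",
      paste(names(x$type_probs), round(x$type_probs, 4),
            sep = "=", collapse = " "), "\n")
  print(df)
  invisible(x)
}

#' Write a motif report as TSV
#'
#' @param stats a \code{motif_stats}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_motif_report <- function(stats, path) {
  df <- data.frame(
    motif = MOTIF_LEVELS,
    count = stats$motif_counts[MOTIF_LEVELS],
    probability = stats$motif_probs[MOTIF_LEVELS],
    preference = stats$preference[MOTIF_LEVELS]
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
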