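#' Find ungapped fragment matches between two genomes
#'
#' A simplified seed-and-extend homology search in the spirit of the
#' high-scoring segment pairs that genome-BLAST distance methods are
#' built on. Exact `k`-mer seeds define candidate diagonals; along each
#' diagonal an ungapped X-drop scan (match +1, mismatch -`mismatch_penalty`,
#' drop `xdrop`) emits maximal locally similar segments, which are trimmed
#' to start and end on a match. Segments shorter than `min_len` are
#' discarded. Finally matches are made non-overlapping on the query:
#' processed in order of decreasing identities (ties by coordinates), each
#' match is trimmed to the longest contiguous run of query positions not
#' yet claimed by a better match.
#'
#' Matching is forward-strand only and per replicon pair; coordinates are
#' 0-based half-open on the replicon.
#'
#' @param a,b [genome_record()]s (or plain DNA strings).
#' @param k Seed length (bp); must be at least 8.
#' @param min_len Minimum match length (bp); at least `k`.
#' @param mismatch_penalty,xdrop X-drop extension parameters.
#' @return A tibble with columns `query_replicon`, `query_start`,
#'   `query_end`, `subject_replicon`, `subject_start`, `subject_end`,
#'   `length`, `identities`.
#' @export
find_fragment_matches <- function(a, b, k = 12L, min_len = 50L,
                                  mismatch_penalty = 3, xdrop = 12) {
  if (k < 8) stopf("`k` must be at least 8")
  if (min_len < k) stopf("`min_len` must be at least `k`")
  reps_a <- if (inherits(a, "genome_record")) a$replicons else c(seq_a = a)
  reps_b <- if (inherits(b, "genome_record")) b$replicons else c(seq_b = b)
  out <- list()
  for (ra in names(reps_a)) {
    for (rb in names(reps_b)) {
      m <- fragment_matches_seq(reps_a[[ra]], reps_b[[rb]], k,
                                mismatch_penalty, xdrop, min_len)
      if (nrow(m)) {
        m$query_replicon <- ra
        m$subject_replicon <- rb
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) {
    return(tibble(query_replicon = character(), query_start = integer(),
                  query_end = integer(), subject_replicon = character(),
                  subject_start = integer(), subject_end = integer(),
                  length = integer(), identities = integer()))
  }
  matches <- bind_rows(out)
  matches <- trim_query_overlaps(matches, min_len, reps_a, reps_b)
  matches[, c("query_replicon", "query_start", "query_end",
              "subject_replicon", "subject_start", "subject_end",
              "length", "identities")]
}

# Raw segment discovery between two sequences (no overlap trimming).
fragment_matches_seq <- function(qs, ss, k, mismatch_penalty, xdrop, min_len) {
  nq <- nchar(qs); ns <- nchar(ss)
  empty <- tibble(query_start = integer(), query_end = integer(),
                  subject_start = integer(), subject_end = integer(),
                  length = integer(), identities = integer())
  if (nq < k || ns < k) return(empty)
  qk <- substring(qs, seq_len(nq - k + 1), seq_len(nq - k + 1) + k - 1)
  sk <- substring(ss, seq_len(ns - k + 1), seq_len(ns - k + 1) + k - 1)
  common <- intersect(qk, sk)
  if (!length(common)) return(empty)
  qpos <- which(qk %in% common)
  spos <- which(sk %in% common)
  qmap <- split(qpos, qk[qpos])
  smap <- split(spos, sk[spos])
  # seed pairs -> diagonals (query_pos - subject_pos), 1-based positions
  diags <- unique(unlist(map(common, function(w) {
    outer(qmap[[w]], smap[[w]], "-")
  }), use.names = FALSE))
  qc <- chars(qs); sc <- chars(ss)
  rows <- list()
  for (dg in sort(diags)) {
    # overlap of the two sequences on this diagonal
    q_from <- max(1L, 1L + dg); q_to <- min(nq, ns + dg)
    len <- q_to - q_from + 1L
    if (len < min_len) next
    eq <- qc[q_from:q_to] == sc[(q_from - dg):(q_to - dg)]
    segs <- xdrop_segments(eq, mismatch_penalty, xdrop)
    if (!nrow(segs)) next
    segs <- segs[segs$len >= min_len, , drop = FALSE]
    if (!nrow(segs)) next
    rows[[length(rows) + 1L]] <- tibble(
      query_start = q_from + segs$from - 2L,        # 0-based half-open
      query_end = q_from + segs$to - 1L,
      subject_start = q_from - dg + segs$from - 2L,
      subject_end = q_from - dg + segs$to - 1L,
      length = segs$len,
      identities = segs$ident
    )
  }
  if (!length(rows)) return(empty)
  bind_rows(rows)
}

# Maximal X-drop segments over a logical match vector. One linear pass:
# a segment ends when the running score drops more than `xdrop` below its
# maximum; segments are trimmed to begin and end on a match.
xdrop_segments <- function(eq, mismatch_penalty, xdrop) {
  n <- length(eq)
  score <- ifelse(eq, 1, -mismatch_penalty)
  from <- integer(); to <- integer(); len <- integer(); ident <- integer()
  i <- 1L
  while (i <= n) {
    if (!eq[i]) { i <- i + 1L; next }
    start <- i
    best <- 0; cur <- 0; best_at <- i - 1L
    j <- i
    while (j <= n) {
      cur <- cur + score[j]
      if (cur > best) { best <- cur; best_at <- j }
      if (best - cur > xdrop) break
      j <- j + 1L
    }
    seg_to <- best_at
    if (seg_to >= start) {
      from <- c(from, start); to <- c(to, seg_to)
      len <- c(len, seg_to - start + 1L)
      ident <- c(ident, sum(eq[start:seg_to]))
    }
    i <- seg_to + 1L
    while (i <= n && !eq[i]) i <- i + 1L
    if (i <= best_at) i <- best_at + 1L
  }
  data.frame(from = from, to = to, len = len, ident = ident)
}

# Greedy resolution of query-side overlaps: better matches (more
# identities) claim their query interval first; later matches keep only
# their longest contiguous unclaimed run, with identities recomputed on
# the retained interval.
trim_query_overlaps <- function(matches, min_len, reps_a, reps_b) {
  ord <- order(-matches$identities, matches$query_replicon,
               matches$query_start, matches$subject_start)
  matches <- matches[ord, ]
  kept <- list()
  claimed <- list()  # per query replicon: logical coverage vector
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    rep <- m$query_replicon
    span <- (m$query_start + 1L):m$query_end  # 1-based positions
    if (is.null(claimed[[rep]])) claimed[[rep]] <- logical(0)
    if (length(claimed[[rep]]) < m$query_end) {
      claimed[[rep]] <- c(claimed[[rep]],
                          logical(m$query_end - length(claimed[[rep]])))
    }
    free <- !claimed[[rep]][span]
    if (!any(free)) next
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    runs_free <- which(runs$values)
    pick <- runs_free[which.max(runs$lengths[runs_free])]
    lo <- starts[pick]; hi <- ends[pick]
    new_len <- hi - lo + 1L
    if (new_len < min_len) next
    offset <- lo - 1L
    m$query_start <- m$query_start + offset
    m$query_end <- m$query_start + new_len
    m$subject_start <- m$subject_start + offset
    m$subject_end <- m$subject_start + new_len
    m$length <- new_len
    if (new_len != matches$length[i]) {
      qsub <- substr(reps_a[[m$query_replicon]], m$query_start + 1L, m$query_end)
      ssub <- substr(reps_b[[m$subject_replicon]], m$subject_start + 1L,
                     m$subject_end)
      m$identities <- sum(chars(qsub) == chars(ssub))
    }
    claimed[[rep]][(m$query_start + 1L):m$query_end] <- TRUE
    kept[[length(kept) + 1L]] <- m
  }
  if (!length(kept)) return(matches[0, ])
  out <- bind_rows(kept)
  arrange(out, .data$query_replicon, .data$query_start)
}
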