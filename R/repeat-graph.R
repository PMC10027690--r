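#' Enumerate flank pairings across a repeat
#'
#' A repeat present in n copies has n upstream and n downstream flanking
#' single-copy sequences; homologous recombination across the repeat can in
#' principle join any upstream flank to any downstream flank. This function
#' enumerates all n^2 combinations and flags the n parental continuities
#' (upstream and downstream flank of the same copy) distinctly from the
#' recombinant ones. For copies in inverted ('-') orientation the flank
#' roles swap, so that e.g. an inverted large repeat bounding a contig is
#' representable.
#'
#' @param copies data.frame with one row per repeat copy: `up_flank`,
#'   `down_flank` (flank labels) and optionally `orientation`
#'   (`"+"`/`"-"`, default `"+"`).
#' @return data.frame with columns `up_flank`, `down_flank`, `parental`.
#' @export
enumerate_flank_pairings <- function(copies) {
  copies <- as.data.frame(copies)
  if (!nrow(copies)) stopf("need at least one repeat copy")
  ori <- if ("orientation" %in% names(copies)) copies$orientation else rep("+", nrow(copies))
  up <- ifelse(ori == "-", copies$down_flank, copies$up_flank)
  dn <- ifelse(ori == "-", copies$up_flank, copies$down_flank)
  n <- nrow(copies)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  data.frame(up_flank = up[grid$i], down_flank = dn[grid$j],
             parental = grid$i == grid$j)
}

#' Check coverage additivity at a repeat
#'
#' In a mixture of genome arrangements sharing a repeat, the read depth of
#' the repeat itself is expected to be approximately the sum of the depths
#' of the single-copy flanking arrangements (e.g. a repeat at ca. 500x
#' flanked by arrangements at ca. 150x and ca. 350x). The check is a simple
#' ratio test: `ratio = repeat coverage / sum(flank coverages)`, passing
#' when `|ratio - 1| <= tolerance`. The ratio is scale-invariant.
#'
#' @param repeat_coverage Mean read depth of the repeat.
#' @param flank_coverages Numeric vector of per-arrangement flank depths.
#' @param tolerance Allowed relative deviation, in (0, 1].
#' @return A list with `expected_sum`, `ratio`, `pass`.
#' @export
coverage_additivity <- function(repeat_coverage, flank_coverages,
                                tolerance = 0.15) {
  if (!length(flank_coverages)) stopf("need at least one flank coverage")
  if (tolerance <= 0 || tolerance > 1) stopf("tolerance must be in (0, 1]")
  s <- sum(flank_coverages)
  if (s == 0) stopf("coverage ratio undefined: flank coverages sum to zero")
  ratio <- repeat_coverage / s
  list(expected_sum = s, ratio = ratio, pass = abs(ratio - 1) <= tolerance)
}

#' Enumerate bounded circular arrangements of a breakpoint graph
#'
#' Models contigs as nodes and recombination breakpoints as (possibly
#' parallel) edges; every simple cycle — a closed walk visiting each contig
#' at most once and using each breakpoint edge at most once — corresponds to
#' a candidate circular genome arrangement. All
#' distinct circles using at most `max_edges` edges are enumerated,
#' deduplicated under rotation and reflection, and truncated at `cap`
#' (breakpoint graphs explode combinatorially).
#'
#' @param edges data.frame with columns `from`, `to` (contig ids) and
#'   optionally `label` (breakpoint name; defaults to `e1..en`).
#' @param max_edges Maximum number of breakpoint edges per circle.
#' @param cap Maximum number of circles returned.
#' @return A list with `circles` (list of data.frames, each an ordered
#'   `node`/`edge` walk) and `truncated` (logical).
#' @export
enumerate_circles <- function(edges, max_edges = 10L, cap = 1000L) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) return(list(circles = list(), truncated = FALSE))
  if (is.null(edges$label)) edges$label <- paste0("e", seq_len(nrow(edges)))
  n_e <- nrow(edges)
  found <- new.env(parent = emptyenv())
  circles <- list()
  truncated <- FALSE

  canon <- function(edge_ids, nodes) {
    # canonical form under rotation and reflection of the closed walk
    k <- length(edge_ids)
    reprs <- character(0)
    for (dir in 1:2) {
      # reflection: the reversed walk visits the nodes in reverse order from
      # the same start and leaves node i via the edge that entered it
      e <- if (dir == 1) edge_ids else rev(edge_ids)
      nd <- if (dir == 1) nodes else c(nodes[1], rev(nodes[-1]))
      for (r in seq_len(k)) {
        er <- c(e[r:k], e[seq_len(r - 1)])
        nr <- c(nd[r:k], nd[seq_len(r - 1)])
        reprs <- c(reprs, paste(paste(nr, er, sep = ":"), collapse = "|"))
      }
    }
    min(reprs)
  }

  walk <- function(start, node, used, edge_path, node_path) {
    if (truncated) return()
    for (i in seq_len(n_e)) {
      if (used[i]) next
      nxt <- if (edges$from[i] == node) edges$to[i]
             else if (edges$to[i] == node) edges$from[i]
             else next
      if (nxt == start && length(edge_path) + 1L >= 2L) {
        key <- canon(c(edge_path, edges$label[i]), c(node_path, node))
        if (is.null(found[[key]])) {
          found[[key]] <- TRUE
          if (length(circles) >= cap) { truncated <<- TRUE; return() }
          circles[[length(circles) + 1L]] <<- data.frame(
            node = c(node_path, node),
            edge = c(edge_path, edges$label[i]))
        }
      }
      if (length(edge_path) + 1L < max_edges && nxt != start &&
          !(nxt %in% c(node_path, node))) {
        u <- used; u[i] <- TRUE
        walk(start, nxt, u, c(edge_path, edges$label[i]), c(node_path, node))
      }
    }
  }

  for (s in unique(c(edges$from, edges$to))) {
    walk(s, s, rep(FALSE, n_e), character(0), character(0))
    if (truncated) break
  }
  list(circles = circles, truncated = truncated)
}

#' Read a repeat-copy table
#'
#' Repeat copies follow the `R<length-in-bp>` naming convention; when an id
#' follows it, the encoded length must match `end - start`.
#'
#' @param path TSV with columns `repeat_id`, `contig`, `start`, `end`
#'   (0-based half-open), `orientation`, `up_flank`, `down_flank`,
#'   `up_coverage`, `down_coverage`.
#' @return data.frame of repeat copies.
#' @export
read_repeat_table <- function(path) {
  if (!file.exists(path)) stopf("repeat table not found: %s", path)
  r <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("repeat_id", "contig", "start", "end", "orientation",
            "up_flank", "down_flank")
  if (!all(need %in% names(r)))
    stopf("repeat table must have columns %s", paste(need, collapse = ", "))
  enc <- suppressWarnings(as.integer(sub("^R", "", r$repeat_id)))
  conv <- grepl("^R[0-9]+$", r$repeat_id)
  bad <- conv & !is.na(enc) & enc != (r$end - r$start)
  if (any(bad)) stopf("repeat id length does not match coordinates for: %s",
                      paste(unique(r$repeat_id[bad]), collapse = ", "))
  r
}
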