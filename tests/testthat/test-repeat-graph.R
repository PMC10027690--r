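test_that("flank pairings enumerate n^2 combinations with n parental", {
  copies <- data.frame(up_flank = c("A", "B"), down_flank = c("C", "D"))
  p <- enumerate_flank_pairings(copies)
  expect_equal(nrow(p), 4)
  key <- paste0(p$up_flank, p$down_flank)
  expect_setequal(key[p$parental], c("AC", "BD"))
  expect_setequal(key[!p$parental], c("AD", "BC"))

  # random instances vs the n^2 oracle
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    copies <- data.frame(up_flank = sprintf("U%d", 1:n),
                         down_flank = sprintf("D%d", 1:n))
    p <- enumerate_flank_pairings(copies)
    expect_equal(nrow(p), n^2)
    expect_equal(sum(p$parental), n)
    expect_setequal(paste0(p$up_flank, p$down_flank),
                    as.vector(outer(copies$up_flank, copies$down_flank, paste0)))
  }
})

test_that("inverted copies swap flank roles", {
  copies <- data.frame(up_flank = c("A", "B"), down_flank = c("C", "D"),
                       orientation = c("+", "-"))
  p <- enumerate_flank_pairings(copies)
  key <- paste0(p$up_flank, p$down_flank)
  expect_setequal(key[p$parental], c("AC", "DB"))
})

test_that("single-copy repeats produce no recombinant pairings", {
  p <- enumerate_flank_pairings(data.frame(up_flank = "A", down_flank = "B"))
  expect_equal(nrow(p), 1)
  expect_true(all(p$parental))
})

test_that("coverage additivity: a 500x repeat flanked by 150x and 350x arrangements", {
  r <- coverage_additivity(500, c(150, 350), tolerance = 0.15)
  expect_equal(r$expected_sum, 500)
  expect_equal(r$ratio, 1.0)
  expect_true(r$pass)

  r2 <- coverage_additivity(300, c(150, 350), tolerance = 0.15)
  expect_equal(r2$ratio, 0.6)
  expect_false(r2$pass)

  r3 <- coverage_additivity(200, 200, tolerance = 0.15)
  expect_equal(r3$ratio, 1.0)

  # scale invariance
  for (c_mult in c(0.1, 3, 100)) {
    rs <- coverage_additivity(500 * c_mult, c(150, 350) * c_mult, 0.15)
    expect_equal(rs$ratio, 1.0)
  }
  expect_error(coverage_additivity(100, 0), "zero")
})

test_that("circle enumeration finds the expected arrangements", {
  # three contigs joined pairwise into one cycle
  tri <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"))
  res <- enumerate_circles(tri)
  expect_equal(length(res$circles), 1)
  expect_equal(nrow(res$circles[[1]]), 3)

  # two contigs sharing two distinct breakpoints: one circle through both
  duo <- data.frame(from = c("A", "A"), to = c("B", "B"),
                    label = c("r1", "r2"))
  res2 <- enumerate_circles(duo)
  expect_equal(length(res2$circles), 1)
  expect_setequal(res2$circles[[1]]$edge, c("r1", "r2"))
})

# brute-force oracle: check every permutation of every edge subset for
# being a valid simple cycle, then deduplicate canonically
oracle_circles <- function(edges) {
  n <- nrow(edges)
  seen <- character(0)
  count <- 0
  subsets <- unlist(lapply(2:n, function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    for (perm in perms(sub)) {
      # orient the walk: start at edges[perm[1],]$from
      ok <- TRUE
      node <- edges$from[perm[1]]
      start <- node
      nodes_seen <- character(0)
      for (e in perm) {
        if (edges$from[e] == node) nxt <- edges$to[e]
        else if (edges$to[e] == node) nxt <- edges$from[e]
        else { ok <- FALSE; break }
        nodes_seen <- c(nodes_seen, node)
        node <- nxt
      }
      if (!ok || node != start) next
      if (anyDuplicated(nodes_seen)) next  # simple cycles only
      k <- length(perm)
      reprs <- character(0)
      lab <- edges$label[perm]
      for (dir in 1:2) {
        e <- if (dir == 1) lab else rev(lab)
        nd <- if (dir == 1) nodes_seen
              else c(nodes_seen[1], rev(nodes_seen[-1]))
        for (r in seq_len(k)) {
          er <- c(e[r:k], e[seq_len(r - 1)])
          nr <- c(nd[r:k], nd[seq_len(r - 1)])
          reprs <- c(reprs, paste(paste(nr, er, sep = ":"), collapse = "|"))
        }
      }
      key <- min(reprs)
      if (!key %in% seen) { seen <- c(seen, key); count <- count + 1 }
    }
  }
  count
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

test_that("circle enumeration matches a brute-force oracle on random graphs", {
  set.seed(17)
  for (rep in 1:15) {
    n_nodes <- sample(2:4, 1)
    n_edges <- sample(2:5, 1)
    nodes <- LETTERS[1:n_nodes]
    edges <- data.frame(from = sample(nodes, n_edges, replace = TRUE),
                        to = sample(nodes, n_edges, replace = TRUE),
                        label = sprintf("e%d", 1:n_edges))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (nrow(edges) < 2) next
    got <- enumerate_circles(edges, max_edges = 10, cap = 1000)
    expect_equal(length(got$circles), oracle_circles(edges))
  }
})

test_that("circle enumeration caps output and flags truncation", {
  # complete multigraph rich in cycles
  edges <- expand.grid(from = LETTERS[1:4], to = LETTERS[1:4],
                       stringsAsFactors = FALSE)
  edges <- edges[edges$from < edges$to, ]
  edges <- rbind(edges, edges)  # parallel copies
  res <- enumerate_circles(edges, max_edges = 8, cap = 5)
  expect_equal(length(res$circles), 5)
  expect_true(res$truncated)
})

test_that("repeat tables validate the R<length> naming convention", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("repeat_id", "contig", "start", "end", "orientation",
                       "up_flank", "down_flank"), collapse = "\t"),
               "R596\tc1\t100\t696\t+\tA\tC",
               "R596\tc2\t50\t646\t+\tB\tD"), f)
  r <- read_repeat_table(f)
  expect_equal(nrow(r), 2)
  writeLines(c(paste(c("repeat_id", "contig", "start", "end", "orientation",
                       "up_flank", "down_flank"), collapse = "\t"),
               "R596\tc1\t100\t600\t+\tA\tC"), f)
  expect_error(read_repeat_table(f), "does not match")
})
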