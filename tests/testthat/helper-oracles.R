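# Independent oracles and random-structure generators used across tests.

# Path-enumeration m-separation oracle: enumerate simple paths; a path
# connects iff every collider lies in the anterior set of the conditioning
# set and every non-collider outside it. Kept deliberately naive and
# independent of the walk-based reachability in the package.
bf_m_separated <- function(g, x, y, C) {
  idx <- seqregraph:::edge_index(g)
  antC <- anterior_set(g, C)
  connected <- FALSE
  rec <- function(node, visited, mark_in) {
    for (e in idx[[node]]) {
      if (e$to %in% visited) next
      if (!is.na(mark_in)) {
        collider <- mark_in && e$mark_here
        ok <- if (collider) node %in% antC else !(node %in% C)
        if (!ok) next
      }
      if (e$to == y) { connected <<- TRUE; return(invisible()) }
      rec(e$to, c(visited, e$to), e$mark_there)
      if (connected) return(invisible())
    }
  }
  rec(x, x, NA)
  !connected
}

# Brute-force anterior set: directed ancestors by path enumeration plus
# full-line connectivity, iterated to a fixpoint.
bf_anterior <- function(g, seeds) {
  out <- unique(seeds)
  repeat {
    new <- out
    for (i in seq_len(nrow(g$arrows)))
      if (g$arrows[i, 2L] %in% new) new <- union(new, g$arrows[i, 1L])
    for (i in seq_len(nrow(g$full))) {
      if (g$full[i, 1L] %in% new) new <- union(new, g$full[i, 2L])
      if (g$full[i, 2L] %in% new) new <- union(new, g$full[i, 1L])
    }
    if (setequal(new, out)) return(intersect(g$nodes, out))
    out <- new
  }
}

random_block_graph <- function(p, p_edge = 0.4) {
  nb <- sample(2:4, 1)
  bx <- sort(sample(0:(nb - 1), p, replace = TRUE))
  bx <- as.integer(factor(bx)) - 1L
  kinds <- rep("response", max(bx) + 1)
  if (max(bx) >= 1 && stats::runif(1) < 0.5) kinds[max(bx) + 1] <- "context"
  nodes <- paste0("v", seq_len(p))
  boxes <- lapply(0:max(bx), function(b)
    lapply(nodes[bx == b], function(nm) variable_spec(nm, 0L, "response")))
  ordering <- block_ordering(boxes, kinds)
  arrows <- dashed <- full <- NULL
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    a <- nodes[i]; b <- nodes[j]
    if (bx[i] == bx[j]) {
      if (kinds[bx[i] + 1] == "response" && stats::runif(1) < p_edge)
        dashed <- rbind(dashed, c(a, b))
      if (kinds[bx[i] + 1] == "context" && stats::runif(1) < p_edge)
        full <- rbind(full, c(a, b))
    } else {
      lo <- if (bx[i] < bx[j]) c(b, a) else c(a, b)
      if (stats::runif(1) < p_edge) arrows <- rbind(arrows, lo)
    }
  }
  regression_graph(ordering, arrows, dashed, full)
}

# direct simulator for a gaussian_system (reduced form), independent of
# simulate_cohort
simulate_system <- function(sys, n) {
  p <- length(sys$order)
  E <- matrix(stats::rnorm(n * p), n) %*% chol(sys$error_cov)
  Y <- t(forwardsolve(diag(p) - sys$coef_matrix, t(E)))
  colnames(Y) <- sys$order
  Y
}

# chain ordering A <- B <- C in three boxes (A is the ultimate response)
chain_graph <- function() {
  ord <- block_ordering(list(
    list(variable_spec("A", 0, "response")),
    list(variable_spec("B", 0, "response")),
    list(variable_spec("Cc", 0, "response"))), rep("response", 3))
  regression_graph(ord, arrows = rbind(c("B", "A"), c("Cc", "B")))
}
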