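#' JC69 transition probability matrix
#'
#' Probability of observing state j at the end of a branch of length `d`
#' (expected substitutions per site) given state i at its start:
#' `1/4 + 3/4 exp(-4d/3)` on the diagonal and `1/4 - 1/4 exp(-4d/3)` off it.
#'
#' @param d Branch length in expected substitutions per site (>= 0).
#' @return A 4x4 row-stochastic matrix (rows/cols A, C, G, T).
#' @examples
#' jc69_transition(0.01)[1, 1] # 0.99007
#' @export
jc69_transition <- function(d) {
  if (!is_scalar_number(d) || d < 0) {
    stop_mscoal("branch length must be a non-negative number")
  }
  e <- exp(-4 * d / 3)
  m <- matrix(0.25 * (1 - e), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- 0.25 + 0.75 * e
  m
}

#' Log-likelihood of one locus on a gene tree (JC69, pruning)
#'
#' Felsenstein pruning with uniform root frequencies: the log of the sum,
#' over all internal-node state assignments, of the product of JC69
#' transition probabilities. Reference R implementation; the MCMC sampler
#' uses an independent compiled core which is tested against this function.
#'
#' @param gt A `gene_tree` whose tip labels match the alignment's row names.
#' @param locus A [locus_data].
#' @return The log-likelihood (0 for a zero-length alignment).
#' @export
locus_loglik <- function(gt, locus) {
  aln <- locus$alignment
  nd <- gt$nodes
  ntip <- sum(!is.na(nd$label))
  tips <- nd$label[seq_len(ntip)]
  if (!setequal(tips, rownames(aln)) || nrow(aln) != ntip) {
    stop_mscoal("gene-tree tips and alignment rows do not match")
  }
  L <- ncol(aln)
  if (L == 0) return(0)
  code <- matrix(match(aln[tips, , drop = FALSE], c("A", "C", "G", "T")),
                 ntip, L)

  # site-pattern compression
  key <- apply(code, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[uniq])))
  pat <- code[, uniq, drop = FALSE]
  npat <- ncol(pat)

  n <- nrow(nd)
  partial <- vector("list", n)
  for (v in seq_len(ntip)) {
    m <- matrix(0, 4, npat)
    m[cbind(pat[v, ], seq_len(npat))] <- 1
    partial[[v]] <- m
  }
  ord <- order(nd$age) # children before parents (tips age 0 first)
  logscale <- rep(0, npat)
  for (v in ord) {
    kids <- which(!is.na(nd$parent) & nd$parent == v)
    if (!length(kids)) next
    m <- matrix(1, 4, npat)
    for (k in kids) {
      d <- nd$age[v] - nd$age[k]
      if (d < 0) stop_mscoal("negative branch length")
      m <- m * (jc69_transition(d) %*% partial[[k]])
    }
    mx <- apply(m, 2, max)
    logscale <- logscale + log(mx)
    partial[[v]] <- sweep(m, 2, mx, "/")
  }
  root <- which(is.na(nd$parent))
  site_ll <- log(colSums(partial[[root]] * 0.25)) + logscale
  sum(site_ll * w)
}

#' Log-density of a gene tree under the MSC / MSci model
#'
#' The coalescent prior of a genealogy on a species network: for each
#' inter-event interval in a population of size `theta` containing `k`
#' lineages a factor `exp(-k(k-1) dt / theta)`, a factor `2/theta` per
#' coalescence, and a factor `phi` (or `1 - phi`) per recorded lineage
#' choice at each introgression event.
#'
#' @param gt A `gene_tree` (node populations and hybrid choices as produced
#'   by [simulate_gene_tree()]).
#' @param net The [species_network] the genealogy lives on (no migration
#'   bands; the IM density is not implemented).
#' @return Log-density.
#' @export
gene_tree_log_density <- function(gt, net) {
  if (nrow(net$bands)) {
    stop_mscoal("gene-tree density with migration bands is not supported")
  }
  pg <- net_pop_graph(net)
  pops <- pg$pops
  pop_id <- stats::setNames(pops$id, pops$pop)
  phi_val <- stats::setNames(pg$phi$value, pg$phi$param)
  nd <- gt$nodes
  n <- nrow(nd)
  tol <- 1e-12

  choice_of <- function(v, param) {
    ch <- gt$choices
    i <- which(ch$node == v & ch$phi_param == param)
    if (!length(i)) NA_character_ else ch$choice[i[1]]
  }

  # walk each branch through the population graph, collecting presence
  # segments per population and the phi factors of recorded choices
  segs <- list()
  logphi <- 0
  for (v in seq_len(n)) {
    if (is.na(nd$parent[v])) next
    pa <- nd$age[nd$parent[v]]
    p <- pop_id[[nd$pop[v]]]
    t <- nd$age[v]
    if (t < pops$lo_age[p] - tol || t > pops$hi_age[p] + tol) {
      stop_mscoal("node ", v, " age outside its population's lifespan")
    }
    repeat {
      top <- pops$hi_age[p]
      segs[[length(segs) + 1L]] <- c(p, t, min(pa, top))
      if (pa <= top + tol) break
      if (pops$trans[p] == "single") {
        p <- pops$to1[p]
      } else if (pops$trans[p] == "choice") {
        ch <- choice_of(v, pops$phi[p])
        if (is.na(ch)) {
          stop_mscoal("branch above node ", v,
                      " crosses an introgression event without a recorded choice")
        }
        ph <- phi_val[[pops$phi[p]]]
        logphi <- logphi + log(if (ch == "donor") ph else 1 - ph)
        p <- if (ch == "donor") pops$to1[p] else pops$to2[p]
      } else {
        stop_mscoal("branch above node ", v, " escapes the root population")
      }
      t <- top
    }
    if (pops$pop[p] != nd$pop[nd$parent[v]]) {
      stop_mscoal("population path of node ", v,
                  " is inconsistent with its parent's population")
    }
  }

  seg <- do.call(rbind, segs)
  logdens <- logphi
  for (p in unique(seg[, 1])) {
    s <- seg[seg[, 1] == p, , drop = FALSE]
    theta <- pops$theta[p]
    pts <- sort(unique(c(s[, 2], s[, 3])))
    if (length(pts) > 1) {
      for (i in seq_len(length(pts) - 1)) {
        k <- sum(s[, 2] <= pts[i] + tol & s[, 3] >= pts[i + 1] - tol)
        logdens <- logdens - k * (k - 1) * (pts[i + 1] - pts[i]) / theta
      }
    }
  }
  ncoal_by_pop <- table(factor(nd$pop[is.na(nd$label)], levels = pops$pop))
  logdens <- logdens + sum(ncoal_by_pop * log(2 / pops$theta))
  logdens
}
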