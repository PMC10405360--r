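#' Locus alignments
#'
#' A `locus_data` holds one multiple-sequence alignment (rows = sequence
#' tags, columns = sites, alphabet strictly A/C/G/T) plus, optionally, the
#' tag-to-species map.
#'
#' @param alignment Character matrix of single letters with row names (tags),
#'   or a named character vector of equal-length sequence strings.
#' @param map Optional [sample_config] (tag -> species).
#' @return An object of class `locus_data`.
#' @export
locus_data <- function(alignment, map = NULL) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    if (is.null(names(alignment))) stop_mscoal("sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) > 1) {
      stop_mscoal("ragged alignment: sequences differ in length")
    }
    alignment <- do.call(rbind, strsplit(alignment, ""))
    rownames(alignment) <- names(lens)
  }
  if (is.null(rownames(alignment))) stop_mscoal("alignment rows must be named")
  if (!all(alignment %in% c("A", "C", "G", "T"))) {
    stop_mscoal("alignment may contain only A, C, G, T")
  }
  structure(list(alignment = alignment, map = map), class = "locus_data")
}

#' @export
print.locus_data <- function(x, ...) {
  cat("<locus_data> ", nrow(x$alignment), " sequences x ",
      ncol(x$alignment), " sites\n", sep = "")
  invisible(x)
}

#' Evolve sequences along a gene tree under JC69
#'
#' The root sequence is i.i.d. uniform over the four nucleotides; each site
#' evolves independently down the tree with JC69 transition probabilities
#' (identity-in-state probability `1/4 + 3/4 exp(-4 d / 3)` over a branch of
#' length `d` expected substitutions per site). Strict clock, no rate
#' variation among sites or loci.
#'
#' @param gt A `gene_tree` (ages in expected substitutions per site).
#' @param L Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return A [locus_data] with one row per tip, in tip order.
#' @export
evolve_jc69 <- function(gt, L, seed = NULL) {
  if (L < 1) stop_mscoal("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nd <- gt$nodes
  n <- nrow(nd)
  ntip <- sum(!is.na(nd$label))
  root <- which(is.na(nd$parent))
  # pre-order: parents before children
  ord <- order(nd$age, decreasing = TRUE)
  seqs <- matrix(0L, n, L)
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  for (v in ord) {
    if (v == root) next
    d <- nd$age[nd$parent[v]] - nd$age[v]
    if (d < 0) stop_mscoal("negative branch length in gene tree")
    pch <- 0.75 * (1 - exp(-4 * d / 3))
    x <- seqs[nd$parent[v], ]
    hit <- which(stats::runif(L) < pch)
    if (length(hit)) {
      x[hit] <- 1L + (x[hit] - 1L +
                        sample.int(3L, length(hit), replace = TRUE)) %% 4L
    }
    seqs[v, ] <- x
  }
  aln <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), , drop = FALSE]],
                ntip, L)
  rownames(aln) <- nd$label[seq_len(ntip)]
  map <- tibble::tibble(tag = nd$label[seq_len(ntip)],
                        species = nd$species[seq_len(ntip)])
  class(map) <- c("sample_config", class(map))
  locus_data(aln, map = map)
}

#' Write / read a multilocus sequential PHYLIP file
#'
#' Loci are stacked as sequential PHYLIP blocks (`ntax nsites` header, then
#' one `tag  sequence` line per sequence), the multilocus layout used by
#' coalescent samplers.
#'
#' @param loci List of [locus_data].
#' @param path File path.
#' @return `write_phylip_multilocus()` returns `path` invisibly;
#'   `read_phylip_multilocus()` returns a list of `locus_data`.
#' @export
write_phylip_multilocus <- function(loci, path) {
  if (inherits(loci, "locus_data")) loci <- list(loci)
  con <- file(path, "w")
  on.exit(close(con))
  for (lc in loci) {
    aln <- lc$alignment
    writeLines(paste(nrow(aln), ncol(aln)), con)
    writeLines(sprintf("%-12s  %s", rownames(aln),
                       apply(aln, 1, paste, collapse = "")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_phylip_multilocus
#' @export
read_phylip_multilocus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  block <- 0L
  loci <- list()
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    block <- block + 1L
    hdr <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    dims <- suppressWarnings(as.integer(hdr))
    if (length(dims) != 2L || anyNA(dims) || any(dims < 1L)) {
      stop_mscoal("malformed PHYLIP header in block ", block, ": '",
                  lines[i], "'")
    }
    i <- i + 1L
    tags <- character(dims[1]); seqs <- character(dims[1])
    for (k in seq_len(dims[1])) {
      while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
      if (i > n) stop_mscoal("truncated PHYLIP block ", block)
      fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(fields) < 2L) {
        stop_mscoal("malformed sequence line in block ", block)
      }
      tags[k] <- fields[1]
      seqs[k] <- paste(fields[-1], collapse = "")
      if (nchar(seqs[k]) != dims[2]) {
        stop_mscoal("block ", block, ", sequence '", tags[k], "': expected ",
                    dims[2], " sites, found ", nchar(seqs[k]))
      }
      i <- i + 1L
    }
    names(seqs) <- tags
    loci[[block]] <- locus_data(seqs)
  }
  loci
}

#' Write loci as FASTA (one file per locus)
#'
#' @param loci List of [locus_data].
#' @param dir Output directory (created if needed); files are
#'   `locus_<i>.fasta`.
#' @return Character vector of file paths, invisibly.
#' @export
write_fasta_loci <- function(loci, dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_mscoal("FASTA output requires the Biostrings package")
  }
  if (inherits(loci, "locus_data")) loci <- list(loci)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(loci), function(i) {
    aln <- loci[[i]]$alignment
    ss <- Biostrings::DNAStringSet(apply(aln, 1, paste, collapse = ""))
    p <- file.path(dir, sprintf("locus_%d.fasta", i))
    Biostrings::writeXStringSet(ss, p)
    p
  }, "")
  invisible(paths)
}
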