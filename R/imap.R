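#' Sequence-tag to species maps (Imap)
#'
#' A sample configuration maps sequence tags (one per sampled haploid
#' sequence) to species names. On disk this is the two-column whitespace
#' separated "Imap" text convention: one `tag species` pair per line.
#'
#' @param counts Named integer vector: number of haploid sequences sampled
#'   per species (e.g. `c(A = 2, B = 2)`). Species with 0 sequences may be
#'   omitted.
#' @param tags Optional explicit tags; by default species `X` with `n`
#'   sequences gets tags `x1 ... xn` (lower-cased species name + index).
#' @return A tibble of class `sample_config` with columns `tag`, `species`.
#' @examples
#' sample_config(c(A = 2, B = 1))
#' @export
sample_config <- function(counts, tags = NULL) {
  if (length(counts) == 0) {
    cfg <- tibble::tibble(tag = character(), species = character())
    class(cfg) <- c("sample_config", class(cfg))
    return(cfg)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_mscoal("`counts` must be a named vector of per-species counts")
  }
  if (any(counts < 0)) stop_mscoal("per-species counts must be >= 0")
  counts <- counts[counts > 0]
  species <- rep(names(counts), counts)
  if (is.null(tags)) {
    tags <- unlist(lapply(names(counts), function(s) {
      paste0(tolower(s), seq_len(counts[[s]]))
    }), use.names = FALSE)
  }
  if (anyDuplicated(tags)) stop_mscoal("duplicate sequence tags")
  cfg <- tibble::tibble(tag = tags, species = species)
  class(cfg) <- c("sample_config", class(cfg))
  cfg
}

#' @rdname sample_config
#' @param cfg A `sample_config`.
#' @return `config_counts()`: named integer vector of sequences per species.
#' @export
config_counts <- function(cfg) {
  if (nrow(cfg) == 0) return(stats::setNames(integer(), character()))
  tab <- table(cfg$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read / write an Imap file
#'
#' @param path File path.
#' @param net Optional [species_network]; if given, every species in the map
#'   must be a sampled (non-ghost) tip of the network.
#' @return [read_imap()]: a `sample_config`.
#' @export
read_imap <- function(path, net = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    cfg <- sample_config(integer())
  } else {
    fields <- strsplit(lines, "[ \t]+")
    bad <- vapply(fields, length, 0L) != 2L
    if (any(bad)) {
      stop_mscoal("Imap line ", which(bad)[1],
                  " does not have exactly two columns")
    }
    tag <- vapply(fields, `[[`, "", 1L)
    species <- vapply(fields, `[[`, "", 2L)
    if (anyDuplicated(tag)) {
      stop_mscoal("duplicate tag(s) in Imap: ",
                  paste(unique(tag[duplicated(tag)]), collapse = ", "))
    }
    cfg <- tibble::tibble(tag = tag, species = species)
    class(cfg) <- c("sample_config", class(cfg))
  }
  if (!is.null(net)) validate_config(cfg, net)
  cfg
}

#' @rdname read_imap
#' @param cfg A `sample_config`.
#' @export
write_imap <- function(cfg, path) {
  writeLines(paste(cfg$tag, cfg$species), path)
  invisible(path)
}

validate_config <- function(cfg, net) {
  ok <- network_tips(net, include_ghost = FALSE)
  bad <- setdiff(unique(cfg$species), ok)
  if (length(bad)) {
    ghosts <- intersect(bad, net$nodes$name[net$nodes$ghost])
    if (length(ghosts)) {
      stop_mscoal("tags map to unsampled ghost species: ",
                  paste(ghosts, collapse = ", "))
    }
    stop_mscoal("tags map to species absent from the network: ",
                paste(bad, collapse = ", "))
  }
  invisible(cfg)
}
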