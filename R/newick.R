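#' Parse an extended-Newick species network
#'
#' Reads a rooted, ultrametric species tree or network in extended Newick.
#' Hybridization (introgression) nodes are tagged with paired `#H<k>` labels:
#' the recipient-side occurrence carries the node's single child, while the
#' donor-side occurrence appears as a leaf beneath the donor node, with the
#' introgression probability `phi` given in the third colon field of that
#' minor edge (`h#H1:0::0.2`). Per-node `theta` may be given inline as a
#' `[&theta=...]` comment or through `attributes`.
#'
#' @param text Extended-Newick string (a single tree, `;`-terminated).
#' @param attributes Optional side information: a list with elements
#'   `theta` (a single value, a named vector, or a data frame with columns
#'   `name`, `theta`) and `bands` (a data frame with columns `donor`,
#'   `recipient`, `rate` and optionally `start`, `end`).
#' @return A [species_network].
#' @examples
#' parse_network("((A:1,B:1):1,C:2);", attributes = list(theta = 0.01))
#' @export
parse_network <- function(text, attributes = NULL) {
  text <- trimws(text)
  if (!nzchar(text)) stop_mscoal("empty Newick string")
  if (!endsWith(text, ";")) stop_mscoal("Newick string must end with ';'")
  toks <- newick_tokens(substr(text, 1, nchar(text) - 1))

  # recursive-descent parse into a flat node table
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$auto <- 0L
  env$i <- 1L

  peek <- function() if (env$i <= length(toks)) toks[[env$i]] else NULL
  advance <- function() {
    t <- toks[[env$i]]
    env$i <- env$i + 1L
    t
  }

  parse_label <- function() {
    out <- list(name = NA_character_, htag = NA_character_,
                theta = NA_real_, len = NA_real_, gamma = NA_real_)
    t <- peek()
    if (!is.null(t) && t$type == "name") {
      advance()
      nm <- t$value
      if (grepl("#", nm, fixed = TRUE)) {
        parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
        out$name <- if (nzchar(parts[1])) parts[1] else NA_character_
        out$htag <- parts[2]
        if (!grepl("^H[0-9]+$", out$htag)) {
          stop_mscoal("malformed hybrid tag '#", out$htag, "'")
        }
      } else {
        out$name <- nm
      }
    }
    t <- peek()
    if (!is.null(t) && t$type == "comment") {
      advance()
      m <- regmatches(t$value, regexec("theta\\s*=\\s*([0-9eE.+-]+)", t$value))[[1]]
      if (length(m) == 2) out$theta <- as.numeric(m[2])
    }
    t <- peek()
    if (!is.null(t) && t$type == ":") {
      advance()
      fields <- character()
      repeat {
        t <- peek()
        if (!is.null(t) && t$type == "number") {
          advance()
          fields <- c(fields, t$value)
        } else {
          fields <- c(fields, NA_character_)
        }
        t <- peek()
        if (!is.null(t) && t$type == ":") advance() else break
      }
      if (length(fields) >= 1 && !is.na(fields[1])) out$len <- as.numeric(fields[1])
      if (length(fields) >= 3 && !is.na(fields[3])) out$gamma <- as.numeric(fields[3])
    }
    out
  }

  parse_subtree <- function() {
    t <- peek()
    kids <- integer()
    if (!is.null(t) && t$type == "(") {
      advance()
      repeat {
        kids <- c(kids, parse_subtree())
        t <- peek()
        if (is.null(t)) stop_mscoal("unbalanced parentheses in Newick string")
        if (t$type == ",") {
          advance()
        } else if (t$type == ")") {
          advance()
          break
        } else {
          stop_mscoal("unexpected token '", t$value, "' in Newick string")
        }
      }
    }
    lab <- parse_label()
    id <- length(env$rows) + 1L
    env$rows[[id]] <- c(lab, list(id = id, children = list(kids)))
    for (k in kids) env$rows[[k]]$parent_id <- id
    id
  }

  root_id <- parse_subtree()
  if (env$i <= length(toks)) stop_mscoal("trailing content in Newick string")
  rows <- env$rows
  n <- length(rows)
  get <- function(f, default) {
    vapply(rows, function(r) r[[f]] %||% default, default)
  }
  name <- get("name", NA_character_)
  htag <- get("htag", NA_character_)
  len <- get("len", NA_real_)
  gamma <- get("gamma", NA_real_)
  theta_in <- get("theta", NA_real_)
  parent_id <- get("parent_id", NA_integer_)
  nkid <- vapply(rows, function(r) length(r$children[[1]]), 0L)

  # merge paired #H occurrences: the occurrence with a child is the
  # recipient-side node; the leaf occurrence marks the donor-side edge
  hyb <- tibble::tibble(label = character(), donor = character(),
                        recipient = character(), phi = numeric())
  drop <- rep(FALSE, n)
  donor_extra <- list() # donor-side node rows to create
  for (tag in unique(stats::na.omit(htag))) {
    occ <- which(!is.na(htag) & htag == tag)
    if (length(occ) != 2L) {
      stop_mscoal("hybrid tag #", tag, " must appear exactly twice (found ",
                  length(occ), ")")
    }
    internal <- occ[nkid[occ] > 0]
    leaf <- occ[nkid[occ] == 0]
    if (length(internal) != 1L || length(leaf) != 1L) {
      stop_mscoal("hybrid tag #", tag,
                  " needs one internal and one leaf occurrence")
    }
    nm <- stats::na.omit(c(name[internal], name[leaf]))
    if (length(unique(nm)) > 1) {
      stop_mscoal("hybrid tag #", tag, " carries conflicting node names")
    }
    phi <- stats::na.omit(c(gamma[leaf], gamma[internal]))
    if (!length(phi)) {
      stop_mscoal("hybrid tag #", tag, " has no phi attribute on its minor edge")
    }
    phi <- phi[1]
    if (is.na(phi) || phi < 0 || phi > 1) {
      stop_mscoal("phi for hybrid #", tag, " must lie in [0, 1]")
    }
    th <- stats::na.omit(c(theta_in[internal], theta_in[leaf]))
    if (length(th)) theta_in[internal] <- th[1]
    if (length(nm)) name[internal] <- nm[1]
    donor_id <- parent_id[leaf]
    if (is.na(donor_id)) stop_mscoal("hybrid leaf #", tag, " cannot be the root")
    drop[leaf] <- TRUE
    hyb <- rbind(hyb, tibble::tibble(
      label = tag, donor = NA_character_, recipient = NA_character_, phi = phi
    ))
    donor_extra[[tag]] <- c(donor_id, internal, leaf)
  }

  # auto-name unnamed (non-dropped) nodes, depth-first order
  auto <- 0L
  for (i in seq_len(n)) {
    if (!drop[i] && is.na(name[i])) {
      repeat {
        auto <- auto + 1L
        cand <- paste0("n", auto)
        if (!cand %in% name) break
      }
      name[i] <- cand
    }
  }

  # ages from branch lengths (root depth 0)
  depth <- rep(NA_real_, n)
  depth[root_id] <- 0
  ord <- order(!is.na(parent_id)) # root first; then fill by repeated passes
  repeat {
    done <- TRUE
    for (i in seq_len(n)) {
      if (is.na(depth[i]) && !is.na(parent_id[i]) && !is.na(depth[parent_id[i]])) {
        if (is.na(len[i])) {
          stop_mscoal("missing branch length above node ",
                      name[i] %||% "(unnamed)")
        }
        depth[i] <- depth[parent_id[i]] + len[i]
        done <- FALSE
      }
    }
    if (done) break
  }
  keep <- which(!drop)
  h <- max(depth[keep])
  age <- h - depth

  # consistency of the two hybrid occurrences: minor edge must hit the same age
  for (tag in names(donor_extra)) {
    ids <- donor_extra[[tag]]
    leaf <- ids[3]; internal <- ids[2]
    if (!is.na(depth[leaf]) && abs(depth[leaf] - depth[internal]) > 1e-8) {
      stop_mscoal("hybrid #", tag, ": the two occurrences of node ",
                  name[internal], " have different ages")
    }
  }

  tipish <- keep[nkid[keep] == 0 & is.na(htag[keep])]
  offtip <- tipish[abs(age[tipish]) > 1e-8]
  if (length(offtip)) {
    stop_mscoal("network is not ultrametric: tip ", name[offtip[1]],
                " has age ", format(age[offtip[1]]))
  }
  age[tipish] <- 0

  # theta from the side table
  th_side <- attributes$theta %||% NULL
  if (!is.null(th_side)) {
    if (is.data.frame(th_side)) {
      idx <- match(name, th_side$name)
      theta_in <- ifelse(is.na(theta_in) & !is.na(idx),
                         th_side$theta[idx], theta_in)
    } else if (is.null(names(th_side)) && length(th_side) == 1L) {
      theta_in[is.na(theta_in)] <- th_side
    } else {
      idx <- match(name, names(th_side))
      theta_in <- ifelse(is.na(theta_in) & !is.na(idx),
                         unname(th_side[idx]), theta_in)
    }
  }

  parent_name <- ifelse(is.na(parent_id), NA_character_, name[parent_id])
  nodes <- tibble::tibble(
    name = name[keep],
    parent = parent_name[keep],
    age = age[keep],
    theta = theta_in[keep],
    ghost = FALSE
  )
  if (any(is.na(nodes$theta))) {
    stop_mscoal("no theta for node(s) ",
                paste(nodes$name[is.na(nodes$theta)], collapse = ", "),
                "; supply inline [&theta=...] or `attributes$theta`")
  }
  for (tag in names(donor_extra)) {
    ids <- donor_extra[[tag]]
    i <- which(hyb$label == tag)
    hyb$donor[i] <- name[ids[1]]
    hyb$recipient[i] <- name[ids[2]]
  }
  species_network(nodes, hybrids = hyb, bands = attributes$bands %||% NULL)
}

newick_tokens <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("(", ")", ",", ":")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch)
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop_mscoal("unterminated [ ] comment in Newick string")
      toks[[length(toks) + 1L]] <- list(
        type = "comment", value = substr(s, i + 1L, i + j - 2L)
      )
      i <- i + j
    } else if (grepl("[ \t\n\r]", ch)) {
      i <- i + 1L
    } else {
      m <- regexpr("^[^(),:\\[\\] \t\n\r]+", substr(s, i, n), perl = TRUE)
      v <- regmatches(substr(s, i, n), m)
      type <- if (grepl("^[+-]?([0-9]|\\.[0-9])", v)) "number" else "name"
      toks[[length(toks) + 1L]] <- list(type = type, value = v)
      i <- i + attr(m, "match.length")
    }
  }
  toks
}

#' Serialize a species network to extended Newick
#'
#' The inverse of [parse_network()]: node ages become branch lengths, every
#' node carries an inline `[&theta=...]` attribute, and each introgression
#' edge is written as a paired `#H<k>` node with `phi` in the third colon
#' field of the minor (donor-side) edge. Migration bands are not part of the
#' Newick dialect; write them separately if present.
#'
#' @param net A [species_network].
#' @param digits Significant digits for ages/attributes (default 17,
#'   round-trip exact for doubles).
#' @return A single Newick string (`;`-terminated).
#' @export
write_network <- function(net, digits = 17) {
  nodes <- net$nodes
  age <- stats::setNames(nodes$age, nodes$name)
  theta <- stats::setNames(nodes$theta, nodes$name)
  hyb <- net$hybrids
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)

  label_of <- function(nm) {
    i <- if (nrow(hyb)) which(hyb$recipient == nm) else integer()
    if (length(i)) paste0(nm, "#", hyb$label[i]) else nm
  }

  root <- network_root(net)
  # children lists include the minor-edge leaves on the donor side
  emit <- function(nm, parent_age) {
    kids <- network_children(net, nm)
    parts <- vapply(kids, emit, "", parent_age = age[nm])
    if (nrow(hyb)) {
      j <- which(hyb$donor == nm)
      for (k in j) {
        parts <- c(parts, paste0(hyb$recipient[k], "#", hyb$label[k],
                                 ":0::", fmt(hyb$phi[k])))
      }
    }
    inner <- if (length(parts)) paste0("(", paste(parts, collapse = ","), ")") else ""
    out <- paste0(inner, label_of(nm), "[&theta=", fmt(theta[nm]), "]")
    if (is.finite(parent_age)) out <- paste0(out, ":", fmt(parent_age - age[nm]))
    out
  }
  paste0(emit(root, Inf), ";")
}
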