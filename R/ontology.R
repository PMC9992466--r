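# Medical-code ontology: a rooted forest over code ids, used both for
# UMLS-style ancestor extension of observed codes and for the
# hierarchical-sigmoid next-day objective.

VIRTUAL_ROOT_PREFIX <- "root|"

virtual_root_id <- function(domain) paste0(VIRTUAL_ROOT_PREFIX, domain)

is_virtual_root <- function(id) startsWith(id, VIRTUAL_ROOT_PREFIX)

#' Build a code ontology from an edge list
#'
#' Constructs a validated forest over the primary parent edges. Each domain
#' (condition, drug, procedure, measurement, ...) gets a virtual root; codes
#' without a primary parent edge hang off their domain's virtual root.
#' Non-primary edges are retained as `extra_parents` and participate only in
#' ancestor extension, never in root paths or the hierarchical loss.
#'
#' @param edges data.frame with columns `child`, `parent`, `primary`
#'   (logical or 0/1) and `domain` (domain of the child code).
#' @return an object of class `ehr_ontology` with components `nodes`,
#'   `domain`, `parent` (named vector, primary parent per node), `children`,
#'   `extra_parents`, `roots` (virtual root ids) and precomputed root paths.
#' @export
build_ontology <- function(edges) {
  edges <- as.data.frame(edges)
  req <- c("child", "parent", "domain")
  if (!all(req %in% names(edges))) {
    stop("ontology edge list needs columns child, parent, primary, domain")
  }
  if (is.null(edges$primary)) edges$primary <- TRUE
  edges$primary <- as.logical(edges$primary)
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges$domain <- as.character(edges$domain)
  # rows with an empty/NA parent declare the child as a root of its domain
  root_rows <- is.na(edges$parent) | edges$parent == ""
  root_decl <- edges[root_rows, , drop = FALSE]
  edges <- edges[!root_rows, , drop = FALSE]

  self <- edges$child == edges$parent
  if (any(self)) {
    stop("cycle in ontology: self-edge at node '", edges$child[self][1], "'")
  }

  prim <- edges[edges$primary, , drop = FALSE]
  dup <- prim$child[duplicated(prim$child)]
  if (length(dup) > 0) {
    stop("node '", dup[1], "' has two primary parents")
  }

  nodes <- unique(c(edges$child, edges$parent, root_decl$child))
  # domain per node: from its child rows, else inherited from descendants
  domain <- rep(NA_character_, length(nodes))
  names(domain) <- nodes
  domain[root_decl$child] <- root_decl$domain
  domain[prim$child] <- prim$domain
  np <- edges[!edges$primary, , drop = FALSE]
  domain[np$child[is.na(domain[np$child])]] <- np$domain[is.na(domain[np$child])]
  # propagate upward until fixed point (parents take a child's domain)
  repeat {
    missing <- names(domain)[is.na(domain)]
    if (length(missing) == 0) break
    filled <- FALSE
    for (m in missing) {
      kid_dom <- domain[prim$child[prim$parent == m]]
      kid_dom <- kid_dom[!is.na(kid_dom)]
      if (length(kid_dom) > 0) {
        domain[m] <- kid_dom[1]
        filled <- TRUE
      }
    }
    if (!filled) {
      domain[is.na(domain)] <- "condition"
      break
    }
  }

  parent <- rep(NA_character_, length(nodes))
  names(parent) <- nodes
  parent[prim$child] <- prim$parent

  # roots: nodes without a primary parent get the per-domain virtual root
  domains <- sort(unique(domain))
  roots <- virtual_root_id(domains)
  names(roots) <- domains
  orphan <- names(parent)[is.na(parent)]
  parent[orphan] <- roots[domain[orphan]]

  all_ids <- c(nodes, unname(roots))
  all_dom <- c(domain, domains)
  names(all_dom) <- all_ids
  parent_full <- c(parent, stats::setNames(rep(NA_character_, length(roots)), roots))

  # cycle check + root paths by iterative parent lookup
  paths <- vector("list", length(all_ids))
  names(paths) <- all_ids
  for (id in nodes) {
    path <- id
    cur <- id
    repeat {
      p <- parent_full[[cur]]
      if (is.na(p)) break
      if (p %in% path) {
        stop("cycle in ontology involving node '", p, "'")
      }
      path <- c(p, path)
      cur <- p
    }
    paths[[id]] <- path
  }
  for (r in roots) paths[[r]] <- r

  children <- split(names(parent_full)[!is.na(parent_full)],
                    parent_full[!is.na(parent_full)])

  extra_parents <- list()
  if (nrow(np) > 0) {
    extra_parents <- split(np$parent, np$child)
  }

  structure(
    list(
      nodes = all_ids,
      domain = all_dom,
      parent = parent_full,
      children = children,
      extra_parents = extra_parents,
      roots = unname(roots),
      paths = paths
    ),
    class = "ehr_ontology"
  )
}

#' @export
print.ehr_ontology <- function(x, ...) {
  n_real <- sum(!is_virtual_root(x$nodes))
  cat("<ehr_ontology> ", n_real, " codes in ", length(x$roots),
      " domain(s); ", length(ontology_leaves(x)), " leaves\n", sep = "")
  invisible(x)
}

#' Real (non virtual-root) codes of an ontology
#' @param ontology an `ehr_ontology`.
#' @export
ontology_codes <- function(ontology) {
  ontology$nodes[!is_virtual_root(ontology$nodes)]
}

#' Leaf codes (codes with no children)
#' @param ontology an `ehr_ontology`.
#' @export
ontology_leaves <- function(ontology) {
  codes <- ontology_codes(ontology)
  codes[!(codes %in% names(ontology$children))]
}

check_known <- function(codes, ontology) {
  unknown <- setdiff(codes, ontology$nodes)
  if (length(unknown) > 0) {
    stop("unknown code(s): ", paste(unknown, collapse = ", "))
  }
}

#' Ancestor extension of a code set
#'
#' Extends a set of observed codes with all their ancestors, following both
#' primary and extra (DAG-style) parent edges. Virtual domain roots are not
#' returned. The operation is idempotent and monotone in its input set.
#'
#' @param codes character vector of code ids.
#' @param ontology an `ehr_ontology`.
#' @return character vector: `codes` plus every ancestor.
#' @export
add_ancestors <- function(codes, ontology) {
  check_known(codes, ontology)
  out <- character(0)
  frontier <- unique(codes)
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    prim <- unname(ontology$parent[frontier])
    extra <- unlist(ontology$extra_parents[frontier], use.names = FALSE)
    frontier <- setdiff(unique(c(prim, extra)), out)
    frontier <- frontier[!is.na(frontier) & !is_virtual_root(frontier)]
  }
  unique(out[!is_virtual_root(out)])
}

#' Root-to-code path along primary edges
#'
#' @param code a single code id.
#' @param ontology an `ehr_ontology`.
#' @return character vector ordered root ... code (virtual root excluded).
#' @export
path_to_root <- function(code, ontology) {
  stopifnot(length(code) == 1L)
  check_known(code, ontology)
  p <- ontology$paths[[code]]
  p[!is_virtual_root(p)]
}

#' Decision-node targets for the hierarchical-sigmoid objective
#'
#' The hierarchical objective factorizes a code set's likelihood into
#' per-node binary decisions. The decision nodes for an observed code set are
#' all children of every node whose subtree intersects the observed set,
#' plus all children of the virtual domain roots; each decision node's
#' target is 1 iff its own subtree intersects the observed set.
#'
#' @param observed character vector of observed code ids (may be empty).
#' @param ontology an `ehr_ontology`.
#' @return named integer vector of 0/1 targets over decision nodes.
#' @export
active_node_targets <- function(observed, ontology) {
  check_known(observed, ontology)
  positives <- character(0)
  if (length(observed) > 0) {
    positives <- unique(unlist(ontology$paths[unique(observed)], use.names = FALSE))
    positives <- positives[!is_virtual_root(positives)]
  }
  expand <- c(positives, ontology$roots)
  decision <- unique(unlist(ontology$children[expand], use.names = FALSE))
  decision <- decision[!is.null(decision)]
  targets <- as.integer(decision %in% positives)
  names(targets) <- decision
  targets
}

#' Read an ontology edge list from CSV
#'
#' Expects one header line and columns `child,parent,primary,domain`.
#'
#' @param path CSV file path.
#' @return an `ehr_ontology`.
#' @export
read_ontology <- function(path) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("child", "parent", "primary", "domain")
  miss <- setdiff(req, names(edges))
  if (length(miss) > 0) {
    stop("ontology file ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  build_ontology(edges)
}

#' Write an ontology's edge list to CSV
#' @param ontology an `ehr_ontology`.
#' @param path output CSV path.
#' @export
write_ontology <- function(ontology, path) {
  parent <- ontology$parent
  keep <- !is.na(parent) & !is_virtual_root(names(parent))
  edges <- data.frame(
    child = names(parent)[keep],
    parent = unname(parent)[keep],
    primary = TRUE,
    domain = unname(ontology$domain[names(parent)[keep]]),
    stringsAsFactors = FALSE
  )
  edges$parent[is_virtual_root(edges$parent)] <- ""
  # drop rows whose parent is a virtual root: they are implicit roots
  edges <- edges[edges$parent != "", , drop = FALSE]
  if (length(ontology$extra_parents) > 0) {
    ep <- ontology$extra_parents
    extra <- data.frame(
      child = rep(names(ep), lengths(ep)),
      parent = unlist(ep, use.names = FALSE),
      primary = FALSE,
      domain = unname(ontology$domain[rep(names(ep), lengths(ep))]),
      stringsAsFactors = FALSE
    )
    edges <- rbind(edges, extra)
  }
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# content hash used to bind encoder checkpoints to the vocabulary they
# were trained on (simple polynomial rolling hash; not cryptographic)
ontology_hash <- function(ontology) {
  s <- paste(ontology$nodes, unname(ontology$parent[ontology$nodes]),
             collapse = ";")
  chars <- utf8ToInt(s)
  h <- 0
  for (chunk in split(chars, ceiling(seq_along(chars) / 1024))) {
    h <- (h * 31 + sum(as.numeric(chunk) * (seq_along(chunk) %% 97 + 1))) %% 2147483647
  }
  sprintf("%d-%d", length(ontology$nodes), as.integer(h))
}

#' Construct a synthetic code ontology
#'
#' Builds a two-level forest per domain: each domain has `n_parents` parent
#' codes, each with `n_leaves_per_parent` leaf children. Leaves are the codes
#' that appear in generated event streams; parents carry the time-invariant
#' outcome signal.
#'
#' @param n_parents parents per domain.
#' @param n_leaves_per_parent leaf children per parent.
#' @param domains character vector of domain names.
#' @return an `ehr_ontology`.
#' @export
make_synthetic_ontology <- function(n_parents = 4L,
                                    n_leaves_per_parent = 4L,
                                    domains = c("condition", "drug",
                                                "procedure", "measurement")) {
  rows <- list()
  for (d in domains) {
    dtag <- toupper(substr(d, 1, 1))
    for (p in seq_len(n_parents)) {
      parent <- sprintf("%s%02d", dtag, p)
      for (l in seq_len(n_leaves_per_parent)) {
        child <- sprintf("%s%02d.%d", dtag, p, l)
        rows[[length(rows) + 1L]] <- data.frame(
          child = child, parent = parent, primary = TRUE, domain = d,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  build_ontology(do.call(rbind, rows))
}
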