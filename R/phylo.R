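# Presence/absence branch assignment on a fixed species tree.
#
# Dollo logic: an insertion arises once and is never precisely excised, so a
# locus present in a set of species maps to the branch above their exclusive
# common ancestor. A branch "matches" a locus when every non-missing species
# below it is present and every non-missing species outside it is absent.

# descendant tip labels for every non-root node (tips included: terminal branches)
branch_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(stats::setNames(list(tree$tip.label), tree$tip.label))
  nodes <- ntip + seq_len(tree$Nnode)
  desc <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- tree$tip.label[t]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]; child <- po[k, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  root <- ntip + 1L
  keep <- setdiff(seq_len(ntip + tree$Nnode), root)
  stats::setNames(desc, branch_labels(tree))[keep]
}

# human-readable branch labels: tip labels for terminal branches, node labels
# where the newick carries them, otherwise the sorted descendant leaf set
branch_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- character(ntip + tree$Nnode)
  labs[seq_len(ntip)] <- tree$tip.label
  node_labs <- tree$node.label %||% rep("", tree$Nnode)
  desc <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- tree$tip.label[t]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    desc[[po[k, 1]]] <- c(desc[[po[k, 1]]], desc[[po[k, 2]]])
  }
  for (i in seq_len(tree$Nnode)) {
    lab <- node_labs[i]
    labs[ntip + i] <- if (!is.na(lab) && nzchar(lab)) lab else
      paste(sort(desc[[ntip + i]]), collapse = "+")
  }
  labs
}

#' Assign a presence/absence pattern to a branch of the species tree
#'
#' Under the Dollo assumption (single insertion event, no precise excision),
#' returns the unique branch -- terminal or internal, excluding the root --
#' whose descendant leaf set consists exactly of the present species. States
#' are `P` (present), `A` (absent), `M` (missing data); up to `max_missing`
#' missing species are tolerated on either side of the boundary. Loci present
#' in the designated outgroup are uninformative and left unassigned.
#'
#' @param states named character vector of states over all tree leaves.
#' @param tree a `phylo` tree (see [read_species_tree()]).
#' @param max_missing maximum number of `M` states tolerated (default 0:
#'   only clear presence/absence boundaries).
#' @param outgroup optional outgroup leaf name; a locus present there is
#'   reported `unassignable`.
#' @return a one-row tibble with `branch` (label or `NA`) and `status`
#'   (`assigned`, `ambiguous`, `unassignable`).
#' @export
assign_branch <- function(states, tree, max_missing = 0L, outgroup = NULL) {
  leaves <- tree$tip.label
  if (!all(names(states) %in% leaves) || !all(leaves %in% names(states))) {
    stop("states must be named by exactly the tree's leaf set")
  }
  states <- states[leaves]
  if (!all(states %in% c("P", "A", "M"))) stop("states must be P, A or M")

  n_missing <- sum(states == "M")
  if (n_missing > max_missing) {
    return(tibble::tibble(branch = NA_character_, status = "ambiguous"))
  }
  present <- leaves[states == "P"]
  if (!length(present)) {
    return(tibble::tibble(branch = NA_character_, status = "unassignable"))
  }
  if (!is.null(outgroup) && outgroup %in% present) {
    return(tibble::tibble(branch = NA_character_, status = "unassignable"))
  }

  desc <- branch_descendants(tree)
  matches <- names(desc)[vapply(desc, function(d) {
    inside <- states[d]; outside <- states[setdiff(leaves, d)]
    all(inside[inside != "M"] == "P") && all(outside[outside != "M"] == "A")
  }, logical(1))]

  if (length(matches) == 1L) {
    tibble::tibble(branch = matches, status = "assigned")
  } else if (length(matches) == 0L) {
    tibble::tibble(branch = NA_character_, status = "unassignable")
  } else {
    tibble::tibble(branch = NA_character_, status = "ambiguous")
  }
}

#' Build a presence/absence matrix of branch-specific insertions
#'
#' For simulation and checks: generates `n` loci per named branch, each
#' present in exactly that branch's descendant species and absent elsewhere.
#'
#' @param tree a `phylo` tree.
#' @param n_per_branch named integer vector; names are branch labels as used
#'   by [assign_branch()] (tip labels or newick node labels).
#' @return a presence-matrix tibble (see [read_presence_matrix()]).
#' @export
presence_from_branches <- function(tree, n_per_branch) {
  desc <- branch_descendants(tree)
  missing <- setdiff(names(n_per_branch), names(desc))
  if (length(missing)) stop("unknown branch label(s): ", paste(missing, collapse = ", "))
  rows <- purrr::imap(n_per_branch, function(n, label) {
    d <- desc[[label]]
    states <- ifelse(tree$tip.label %in% d, "P", "A")
    tibble::as_tibble(c(
      list(locus = paste0(label, "_", seq_len(n))),
      stats::setNames(lapply(states, rep, times = n), tree$tip.label)))
  })
  dplyr::bind_rows(rows)
}

#' Per-branch insertion counts and fractions
#'
#' Assigns every locus of a presence/absence matrix to a branch and tallies
#' counts; fractions are percentages of all assigned loci (ambiguous and
#' unassignable loci excluded), rounded to the nearest integer.
#'
#' @param matrix tibble from [read_presence_matrix()]: `locus` column plus
#'   one `P`/`A`/`M` column per species.
#' @param tree a `phylo` tree.
#' @param max_missing see [assign_branch()].
#' @param outgroup see [assign_branch()].
#' @return a tibble with `branch`, `count`, `pct`, with attributes
#'   `n_assigned`, `n_ambiguous`, `n_unassignable` and class
#'   `branch_counts`.
#' @export
branch_counts <- function(matrix, tree, max_missing = 0L, outgroup = NULL) {
  species <- setdiff(names(matrix), "locus")
  assignments <- purrr::map_dfr(seq_len(nrow(matrix)), function(i) {
    states <- unlist(matrix[i, species])
    res <- assign_branch(states, tree, max_missing = max_missing, outgroup = outgroup)
    res$locus <- matrix$locus[i]
    res
  })
  assigned <- assignments[assignments$status == "assigned", ]
  out <- dplyr::count(assigned, branch = .data$branch, name = "count")
  out$pct <- round(100 * out$count / sum(out$count))
  structure(out,
            n_assigned = nrow(assigned),
            n_ambiguous = sum(assignments$status == "ambiguous"),
            n_unassignable = sum(assignments$status == "unassignable"),
            assignments = assignments,
            class = c("branch_counts", class(out)))
}
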