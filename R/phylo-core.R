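#' Parse a Newick string into a phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ordinary `"phylo"` object; all functions in this package consume and
#' return that class. Tip labels must be unique and non-empty, and branch
#' lengths must be non-negative; branches with no length in the input are set
#' to zero with a warning so that downstream distance computations remain
#' defined.
#'
#' @param text A single Newick string (terminated by `;`). Quoted labels are
#'   supported.
#' @return A `"phylo"` tree with an `edge.length` vector (zeros filled in
#'   where the input omitted lengths). Internal node labels, when present,
#'   are kept as support annotations in `node.label` and never treated as
#'   taxa.
#' @seealso [write_newick()], [read_newick()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found in string",
                        call. = FALSE)
  # ape keeps the surrounding quotes of quoted labels; store the bare text
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2, nchar(x[q]) - 1), fixed = TRUE)
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning(sum(is.na(tr$edge.length)),
            " branch length(s) missing; set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  validate_tree(tr)
  tr
}

# Light structural scan so malformed input fails with a character offset
# (ape's own parser dies with less useful messages or silently misreads).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i,
             call. = FALSE)
    }
  }
  if (in_quote)
    stop("Newick parse error: unterminated quoted label", call. = FALSE)
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Read a Newick file
#'
#' @param path Path to a file holding one Newick tree.
#' @return A validated `"phylo"` tree (see [parse_newick()]).
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Validate the structural invariants of a tree
#'
#' Checks that tip labels are unique and non-empty, branch lengths are
#' non-negative, and the edge table describes a single connected rooted tree.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label(s)")
  if (anyDuplicated(tl))
    stop("duplicate tip name(s): ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  n <- length(tl)
  # every node except the root has exactly one parent edge
  kids <- tabulate(tree$edge[, 2], nbins = n + tree$Nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1L) stop("tree does not have a unique root")
  if (any(kids[-root] != 1L)) stop("tree is not connected and acyclic")
  invisible(tree)
}

#' Serialize a tree to a Newick string
#'
#' Writes branch lengths at full double precision (`%.15g`) so that
#' write-then-parse round trips are lossless for topology, lengths and
#' labels. Labels containing characters outside `[A-Za-z0-9_.-]` are wrapped
#' in single quotes (internal quotes doubled), so quoted input labels such as
#' `'sp. nov.'` survive a round trip.
#'
#' @param tree A valid `"phylo"` tree.
#' @return A single Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(x) {
    if (grepl("^[A-Za-z0-9_.-]+$", x)) x
    else paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  }
  node_lab <- tree$node.label
  fmt <- function(node, len) {
    if (node <= n) {
      core <- lab(tree$tip.label[node])
    } else {
      sub <- vapply(children[[as.character(node)]], function(e)
        fmt(tree$edge[e, 2], tree$edge.length[e]), character(1))
      nl <- if (!is.null(node_lab)) node_lab[node - n] else ""
      if (is.na(nl)) nl <- ""
      core <- paste0("(", paste(sub, collapse = ","), ")",
                     if (nzchar(nl)) lab(nl) else "")
    }
    if (is.na(len)) core else paste0(core, ":", sprintf("%.15g", len))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  paste0(fmt(root, NA), ";")
}

#' Patristic distance matrix of a tree
#'
#' The patristic distance between two tips is the sum of branch lengths along
#' the path connecting them; it is unchanged by rerooting, which is why all
#' community and congruence metrics here consume distance matrices rather
#' than trees directly.
#'
#' @param tree A `"phylo"` tree with at least 2 tips.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named and ordered by `tree$tip.label`.
#' @export
#' @examples
#' patristic_matrix(parse_newick("((A:1,B:1):1,C:2);"))
patristic_matrix <- function(tree) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  diag(d) <- 0
  d
}

#' Validate a labelled distance matrix
#'
#' @param d A square numeric matrix with identical, unique row and column
#'   names, symmetric to a relative tolerance of 1e-12, zero diagonal.
#' @return The matrix (symmetrized exactly), invisibly usable downstream.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d)) stop("distance matrix must be numeric")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  labs <- rownames(d)
  if (is.null(labs) || is.null(colnames(d)) || !identical(labs, colnames(d)))
    stop("distance matrix must carry identical row and column names")
  if (anyDuplicated(labs)) stop("duplicate labels in distance matrix")
  scale <- max(abs(d), 1, na.rm = TRUE)
  if (!identical(is.na(d), is.na(t(d))) ||
      max(abs(d - t(d)), 0, na.rm = TRUE) > 1e-12 * scale)
    stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0")
  if (any(d[!is.na(d)] < 0)) stop("negative distances")
  (d + t(d)) / 2
}

#' TN93 nucleotide distances from an alignment
#'
#' Tamura-Nei (1993) pairwise distances, optionally gamma-corrected for
#' among-site rate variation, computed with [ape::dist.dna()] under pairwise
#' deletion of sites containing gaps or ambiguities. Pairs whose distance is
#' undefined (saturation makes a logarithm argument non-positive, or the pair
#' shares no comparable sites) are returned as `NA` and listed in the
#' `"undefined_pairs"` attribute; [neighbor_joining()] refuses such matrices,
#' so saturated pairs must be resolved (or taxa dropped) before tree
#' building.
#'
#' @param alignment A `DNAbin` matrix, or a named character vector of
#'   equal-length DNA sequences (A/C/G/T/N/- case-insensitive).
#' @param gamma_shape Positive shape of the gamma rate distribution, or
#'   `NULL` (default) for the uncorrected distance. Large shapes approach the
#'   uncorrected value.
#' @return A symmetric distance matrix (possibly containing `NA`), with
#'   attribute `undefined_pairs`: a two-column character matrix of pairs
#'   whose distance is undefined (zero rows when all are defined).
#' @export
tn93_distance <- function(alignment, gamma_shape = NULL) {
  aln <- as_dnabin(alignment)
  if (!is.null(gamma_shape)) {
    stopifnot(is.numeric(gamma_shape), length(gamma_shape) == 1L,
              gamma_shape > 0)
  }
  labs <- rownames(aln)
  # pairs sharing no comparable site are a hard error: no distance exists
  comparable <- pairwise_comparable_sites(aln)
  if (any(comparable[upper.tri(comparable)] == 0)) {
    bad <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)
    stop("no comparable sites for pair(s): ",
         paste(labs[bad[, 1]], labs[bad[, 2]], sep = "/", collapse = ", "))
  }
  d <- suppressWarnings(ape::dist.dna(
    aln, model = "TN93",
    gamma = if (is.null(gamma_shape)) FALSE else gamma_shape,
    pairwise.deletion = TRUE, as.matrix = TRUE))
  d <- d[labs, labs, drop = FALSE]
  diag(d) <- 0
  und <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  d[!is.finite(d)] <- NA_real_
  up <- cbind(labs[und[, 1]], labs[und[, 2]])
  colnames(up) <- c("taxon_a", "taxon_b")
  if (nrow(up) > 0)
    warning("TN93 distance undefined (saturation) for ", nrow(up), " pair(s)")
  attr(d, "undefined_pairs") <- up
  d
}

as_dnabin <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    aln <- as.matrix(alignment)
  } else if (is.character(alignment)) {
    if (is.null(names(alignment))) stop("sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) stop("sequences must have equal length")
    m <- t(vapply(alignment,
                  function(s) strsplit(tolower(s), "")[[1]],
                  character(lens[1])))
    bad <- setdiff(unique(as.vector(m)), c("a", "c", "g", "t", "n", "-"))
    if (length(bad)) stop("unsupported symbols: ", paste(bad, collapse = " "))
    aln <- ape::as.DNAbin(m)
  } else stop("alignment must be a DNAbin object or named character vector")
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  aln
}

pairwise_comparable_sites <- function(aln) {
  m <- toupper(as.character(as.matrix(aln)))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  okn <- matrix(as.numeric(ok), nrow = nrow(m))
  okn %*% t(okn)
}

#' Read a DNA alignment from FASTA
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @return A `DNAbin` matrix suitable for [tn93_distance()].
#' @export
read_alignment <- function(path) {
  as.matrix(ape::read.FASTA(path))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]. Negative estimated
#' branch lengths (a known artefact of NJ on noisy distances) are clamped to
#' zero with a warning, because all downstream metrics require non-negative
#' patristic distances. The returned tree carries the arbitrary root NJ
#' leaves it with, flagged via `attr(tree, "unrooted") == TRUE`.
#'
#' @param d A labelled distance matrix over at least 3 taxa, no `NA` entries.
#' @return A `"phylo"` tree with attribute `unrooted = TRUE`.
#' @export
neighbor_joining <- function(d) {
  d <- validate_distance_matrix(d)
  if (anyNA(d)) stop("distance matrix has undefined entries; resolve ",
                     "saturated pairs before neighbour joining")
  if (nrow(d) < 3L)
    stop("need at least 3 taxa; connect 2 taxa with a single branch of ",
         "length d directly")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  attr(tr, "unrooted") <- TRUE
  tr
}

# tips descending from each node, as an index list over 1..(n + Nnode)
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  # edges in ape postorder visit children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    out[[eo[k, 1]]] <- c(out[[eo[k, 1]]], out[[eo[k, 2]]])
  lapply(out, function(x) sort(unique(x[x <= n])))
}

#' Check a family map against a tree
#'
#' @param tree A `"phylo"` tree.
#' @param families Named character vector: names are tip labels, values are
#'   family names. Every tip must appear exactly once.
#' @return Invisibly, a list with per-family tip indices and the crown node
#'   (MRCA) of each family; errors when coverage fails or any family is not
#'   monophyletic.
#' @export
check_family_map <- function(tree, families) {
  validate_tree(tree)
  if (is.null(names(families)) || !is.character(families))
    stop("families must be a named character vector (tip -> family)")
  tl <- tree$tip.label
  missing <- setdiff(tl, names(families))
  extra <- setdiff(names(families), tl)
  if (length(missing)) stop("tips without family: ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("family map names not in tree: ",
                          paste(extra, collapse = ", "))
  if (anyDuplicated(names(families))) stop("duplicate tips in family map")
  desc <- descendant_tips(tree)
  fams <- split(match(names(families), tl), unname(families))
  crowns <- integer(length(fams))
  names(crowns) <- names(fams)
  for (f in names(fams)) {
    tips <- sort(fams[[f]])
    if (length(tips) == 1L) {
      crowns[f] <- tips
      next
    }
    mrca <- ape::getMRCA(tree, tips)
    if (!identical(desc[[mrca]], tips))
      stop("family '", f, "' is not monophyletic; clade of its MRCA also ",
           "contains: ",
           paste(tl[setdiff(desc[[mrca]], tips)], collapse = ", "))
    crowns[f] <- mrca
  }
  invisible(list(tips = fams, crowns = crowns, descendants = desc))
}

#' Stretch the deep (between-family) branches of a tree
#'
#' Multiplies by `factor` the branch lengths of the deep part of the tree --
#' every branch that is not inside a family clade, i.e. the spanning system
#' connecting family crown nodes to the root, including each family's stem
#' branch. This mimics a simplistic correction for underestimated deep
#' divergences (e.g. transitional saturation in a fast mitochondrial
#' marker): within-family patristic distances are untouched while
#' between-family distances grow. Alternatively `which = "stems"` stretches
#' only each family's stem branch.
#'
#' @param tree A `"phylo"` tree in which every family is monophyletic.
#' @param families Named character vector mapping every tip to a family.
#' @param factor Multiplier, >= 1.
#' @param which `"deep"` (default) stretches all branches outside family
#'   clades; `"stems"` stretches only the stem branch of each family crown.
#' @return The perturbed tree.
#' @export
stretch_deep_branches <- function(tree, families, factor,
                                  which = c("deep", "stems")) {
  which <- match.arg(which)
  stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 1)
  fm <- check_family_map(tree, families)
  n <- length(tree$tip.label)
  inside <- rep(FALSE, nrow(tree$edge))
  # nodes strictly inside a family clade: the crown and its descendants
  inside_nodes <- unlist(lapply(fm$crowns, function(cr) {
    if (cr <= n) integer(0) else {
      all_desc <- which_nodes_under(tree, cr)
      c(cr, all_desc)
    }
  }))
  inside <- tree$edge[, 1] %in% inside_nodes
  target <- if (which == "deep") !inside
            else tree$edge[, 2] %in% fm$crowns
  out <- tree
  out$edge.length[target] <- out$edge.length[target] * factor
  out
}

# all nodes (internal and tips) strictly below `node`
which_nodes_under <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  acc <- integer(0)
  stack <- kids[[as.character(node)]]
  while (length(stack)) {
    x <- stack[[1]]
    stack <- stack[-1]
    acc <- c(acc, x)
    ch <- kids[[as.character(x)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  acc
}

#' Shuffle taxon labels among the tips of a tree
#'
#' Negative-control perturbation: topology and branch lengths are unchanged,
#' but tip names are permuted uniformly at random, destroying any real
#' association between taxa and tree position while preserving the multiset
#' of pairwise patristic distances.
#'
#' @param tree A `"phylo"` tree.
#' @param seed Integer seed; the same seed always yields the same labelling.
#' @return The relabelled tree.
#' @export
shuffle_tips <- function(tree, seed) {
  validate_tree(tree)
  with_seed(seed, {
    tree$tip.label <- sample(tree$tip.label)
  })
  tree
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
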