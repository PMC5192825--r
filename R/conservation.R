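#' Count substitutions at one alignment column
#'
#' Two counting semantics are provided. `"distinct"` (the default) counts the
#' number of different amino acids observed at the position, so an invariant
#' column scores 1 and per-gene mean rates are strictly positive — which
#' keeps the evolutionary weight 1/R finite. `"fitch"` computes the minimum
#' number of state changes on the tree by unweighted parsimony; on
#' multifurcating trees the Hartigan generalisation of the two-pass Fitch
#' count is used, which is exact for arbitrary (not just binary) trees.
#'
#' @param column named character vector of residues keyed by taxon; gaps
#'   (`-`) and ambiguous residues (`X`) are dropped before counting.
#' @param tree a time tree containing all taxa of `column` (only consulted in
#'   `"fitch"` mode; the pruning to the column's taxa happens internally).
#' @param mode `"distinct"` or `"fitch"`.
#' @return integer substitution count `s` (distinct: >= 1; fitch: >= 0).
#' @export
count_substitutions <- function(column, tree = NULL,
                                mode = c("distinct", "fitch")) {
  mode <- match.arg(mode)
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  if (is.null(names(column)) || any(!nzchar(names(column))))
    stop("column residues must be named by taxon", call. = FALSE)
  keep <- column %in% AA20
  column <- column[keep]
  if (length(column) == 0L)
    stop("no ungapped, unambiguous residues in column", call. = FALSE)
  if (mode == "distinct") return(length(unique(column)))
  if (is.null(tree)) stop("fitch mode requires a tree", call. = FALSE)
  absent <- setdiff(names(column), tree$tip.label)
  if (length(absent))
    stop("column taxa not in tree: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (length(column) == 1L) return(0L)
  sub <- prune_to_taxa(tree, names(column))
  fitch_hartigan_count(sub, column)
}

# Hartigan (1973) bottom-up pass: at an internal node with k children whose
# preliminary sets contain a given state in cnt[state] children, the minimum
# changes below the node increase by k - max(cnt), and the preliminary set is
# argmax(cnt).  Reduces to classic Fitch on binary trees; exact on polytomies.
#' @keywords internal
fitch_hartigan_count <- function(tree, states) {
  states <- states[tree$tip.label]
  state_levels <- unique(states)
  ns <- length(state_levels)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  n_children <- tabulate(edge[, 1], nbins = nnode)
  cnt <- matrix(0L, nnode, ns)
  finalized <- logical(nnode)
  changes <- 0L
  child_set <- function(v) {
    if (v <= ntip) {
      s <- integer(ns)
      s[match(states[v], state_levels)] <- 1L
      return(s)
    }
    k <- max(cnt[v, ])
    changes <<- changes + n_children[v] - k
    as.integer(cnt[v, ] == k)
  }
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 2]
    set <- child_set(v)
    cnt[edge[e, 1], ] <- cnt[edge[e, 1], ] + set
  }
  root <- edge[nrow(edge), 1]
  changes <- changes + n_children[root] - max(cnt[root, ])
  changes
}

#' Per-site absolute substitution rates
#'
#' For every alignment column where the reference taxon carries a residue,
#' the tree is pruned to the taxa without a gap at that column; the
#' evolutionary time span `t` is the total branch length of the pruned tree
#' (Myr), the substitution count `s` comes from [count_substitutions()], and
#' the absolute substitution rate is `r = 1000 * s / t` in substitutions per
#' billion years. Columns with fewer than two ungapped taxa have no
#' evolutionary span and are flagged missing (excluded from the gene mean).
#'
#' @param alignment a [protein_alignment()].
#' @param tree a time tree (Myr) whose leaves cover the alignment taxa.
#' @param mode substitution counting mode, see [count_substitutions()].
#' @param fitch_zero rate floor used in `"fitch"` mode for zero-change
#'   columns, expressed as an effective substitution count (default 0.5, i.e.
#'   `r = 0.5 * 1000 / t`), so conservation stays finite and ordered.
#' @return data.frame with columns `column` (0-based alignment column),
#'   `s`, `t`, `r`, `n_taxa_ungapped`, `missing`.
#' @export
site_rates <- function(alignment, tree, mode = c("distinct", "fitch"),
                       fitch_zero = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "protein_alignment"))
  validate_time_tree(tree)
  absent <- setdiff(rownames(alignment), tree$tip.label)
  if (length(absent))
    stop("alignment taxa not in tree: ", paste(absent, collapse = ", "),
         call. = FALSE)
  ref <- alignment_reference(alignment)
  ref_row <- alignment[ref, ]
  cols <- which(ref_row %in% AA20)
  if (length(cols) == 0L)
    stop("reference taxon '", ref, "' has no unambiguous residues",
         call. = FALSE)
  span_cache <- new.env(parent = emptyenv())
  out <- data.frame(column = cols - 1L, s = NA_real_, t = NA_real_,
                    r = NA_real_, n_taxa_ungapped = 0L, missing = TRUE)
  for (k in seq_along(cols)) {
    col <- alignment[, cols[k]]
    col <- col[col %in% AA20]
    n <- length(col)
    out$n_taxa_ungapped[k] <- n
    if (n < 2L) next
    key <- paste(sort(names(col)), collapse = "\r")
    t_span <- span_cache[[key]]
    if (is.null(t_span)) {
      t_span <- total_tree_length(prune_to_taxa(tree, names(col)))
      span_cache[[key]] <- t_span
    }
    if (t_span <= 0) next  # zero span: no observable time, leave missing
    s <- count_substitutions(col, tree, mode)
    r <- if (mode == "fitch" && s == 0L) fitch_zero * 1000 / t_span
         else 1000 * s / t_span
    out$s[k] <- s
    out$t[k] <- t_span
    out$r[k] <- r
    out$missing[k] <- FALSE
  }
  out
}

#' Gene-level evolutionary rate and weight
#'
#' Averages per-site absolute substitution rates into the gene-level
#' evolutionary rate `R` (substitutions/Byr over counted positions) and its
#' reciprocal, the evolutionary weight `WE = 1/R`. Low `R` means high
#' conservation, hence large weight.
#'
#' @param rates data.frame from [site_rates()].
#' @param gene_id identifier recorded in the output.
#' @return one-row data.frame: `gene_id`, `L` (reference-sequence length),
#'   `L_effective` (columns entering the mean), `R`, `WE`.
#' @export
gene_rate <- function(rates, gene_id = NA_character_) {
  ok <- !rates$missing
  if (!any(ok))
    stop("all sites missing for gene '", gene_id,
         "': cannot estimate a rate", call. = FALSE)
  R <- mean(rates$r[ok])
  if (!(R > 0))
    stop("gene '", gene_id, "' has zero mean rate; evolutionary weight ",
         "undefined", call. = FALSE)
  data.frame(gene_id = gene_id, L = nrow(rates), L_effective = sum(ok),
             R = R, WE = 1 / R)
}

#' Gene rates for a set of alignments
#'
#' @param alignments named list of [protein_alignment()] objects (names are
#'   gene ids) or a directory of aligned FASTA files (`*.fa`, `*.fasta`;
#'   gene id = file stem).
#' @param tree time tree in Myr.
#' @param reference reference taxon (used when reading from a directory).
#' @param mode,fitch_zero see [site_rates()].
#' @param alias optional taxon alias table, see [read_protein_alignment()].
#' @return data.frame with one row per gene (columns of [gene_rate()]).
#' @export
gene_rates <- function(alignments, tree, reference = NULL,
                       mode = c("distinct", "fitch"), fitch_zero = 0.5,
                       alias = NULL) {
  mode <- match.arg(mode)
  if (is.character(alignments) && length(alignments) == 1L &&
      dir.exists(alignments)) {
    files <- list.files(alignments, pattern = "\\.(fa|fasta)$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no FASTA files in ", alignments, call. = FALSE)
    if (is.null(reference))
      stop("reference taxon required when reading a directory", call. = FALSE)
    alignments <- lapply(files, read_protein_alignment, reference = reference,
                         alias = alias)
    names(alignments) <- sub("\\.(fa|fasta)$", "", basename(files))
  }
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  do.call(rbind, lapply(names(alignments), function(g) {
    gene_rate(site_rates(alignments[[g]], tree, mode, fitch_zero), g)
  }))
}
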