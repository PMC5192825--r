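# Synthetic-data generators.  These emulate the shape of the real use case
# — a time-calibrated vertebrate tree, reference-anchored protein
# alignments, and an imbalanced clinical/molecular cohort where a small
# informative subset hides among many noise features and informativeness
# correlates with conservation — so the full pipeline is testable with
# known ground truth and no external downloads.

#' Simulate an ultrametric time tree
#'
#' Coalescent-style random topology with node depths rescaled so every leaf
#' sits exactly `depth_myr` below the root (all taxa sampled in the
#' present).
#'
#' @param n_taxa number of leaves (>= 2).
#' @param depth_myr root-to-leaf distance in million years (default 500,
#'   the order of vertebrate-wide divergence).
#' @param seed integer seed.
#' @return a `phylo` time tree with leaves `t1..tn`.
#' @export
simulate_timetree <- function(n_taxa, depth_myr = 500, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  stopifnot(depth_myr > 0)
  with_seed(seed, {
    if (n_taxa == 2L) {
      tree <- parse_newick(sprintf("(t1:%g,t2:%g);", depth_myr, depth_myr))
    } else {
      tree <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length * depth_myr / depth
    }
    tree
  })
}

#' Simulate a protein alignment on a time tree
#'
#' Poisson substitution process over the 20 amino acids: the root sequence
#' is uniform, each branch applies `Poisson(rate * branch_myr / 1000)`
#' substitution events per site (rates in substitutions/Byr), each event
#' replacing the state uniformly among the other 19. Gaps are inserted
#' independently per taxon and site. This deliberately simple model is
#' sufficient for rate-recovery tests; no empirical exchangeability matrix
#' is used.
#'
#' @param tree a time tree in Myr.
#' @param site_rate_profile per-column true rates (subst/Byr), length =
#'   alignment length.
#' @param gap_prob per-taxon, per-site gap probability in \[0, 1).
#' @param seed integer seed.
#' @param reference reference taxon (default: first tip).
#' @return a [protein_alignment()].
#' @export
simulate_alignment <- function(tree, site_rate_profile, gap_prob = 0,
                               seed = NULL, reference = NULL) {
  stopifnot(all(site_rate_profile >= 0), gap_prob >= 0, gap_prob < 1)
  L <- length(site_rate_profile)
  ntip <- length(tree$tip.label)
  if (is.null(reference)) reference <- tree$tip.label[1]
  with_seed(seed, {
    edge <- stats::reorder(tree, "cladewise")$edge
    elen <- stats::reorder(tree, "cladewise")$edge.length
    nnode <- ntip + tree$Nnode
    seqs <- matrix(NA_integer_, nnode, L)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(20L, L, replace = TRUE)
    for (e in seq_len(nrow(edge))) {
      parent_seq <- seqs[edge[e, 1], ]
      k <- stats::rpois(L, site_rate_profile * elen[e] / 1000)
      child_seq <- parent_seq
      for (i in which(k > 0)) {
        s <- child_seq[i]
        for (j in seq_len(k[i])) {
          s <- sample.int(19L, 1L)
          s <- s + (s >= child_seq[i])  # uniform over the other 19 states
          child_seq[i] <- s
        }
      }
      seqs[edge[e, 2], ] <- child_seq
    }
    mat <- matrix(AA20[seqs[seq_len(ntip), , drop = FALSE]], ntip, L)
    rownames(mat) <- tree$tip.label
    if (gap_prob > 0) {
      gaps <- matrix(stats::runif(ntip * L) < gap_prob, ntip, L)
      mat[gaps] <- "-"
    }
    protein_alignment(mat, reference)
  })
}

#' Simulate a clinical/molecular cohort with planted structure
#'
#' Generates an imbalanced binary cohort in the image of the real datasets
#' the method targets: a small informative subset among many noise
#' features, a clinical block, and gene-level conservation that correlates
#' with informativeness. Informative features shift their class means by
#' `effect_size` standard deviations; informative genes are assigned a low
#' evolutionary rate (high WE) with probability `conservation_coupling`,
#' otherwise all rates come from a broad background distribution.
#'
#' @param m number of samples.
#' @param p total number of features (molecular + `n_clinical` clinical).
#' @param n_informative planted informative molecular features.
#' @param effect_size class-mean shift in sd units (default 1).
#' @param class_balance fraction of positive (poor-outcome) samples
#'   (default 0.3, the imbalance regime the undersampling wrapper exists
#'   for).
#' @param conservation_coupling probability that an informative gene is
#'   conserved (default 0.9).
#' @param noise_correlation number of noise features resampled until they
#'   show a spurious nominal association (p < 0.05) with the outcome —
#'   emulating the fortuitous statistical hits of finite omics cohorts.
#' @param n_clinical clinical covariates, simulated with a moderate effect
#'   (half of `effect_size`), exercising the max-WE rule (default 5).
#' @param seed integer seed.
#' @return list: `matrix` ([labeled_matrix()], unnormalized), `meta`
#'   (feature metadata), `conservation` (gene-rate table with columns
#'   `gene_id`, `R`, `WE`), `truth` (list with `informative` feature ids
#'   and the per-gene true `R`).
#' @export
simulate_cohort <- function(m, p, n_informative, effect_size = 1,
                            class_balance = 0.3,
                            conservation_coupling = 0.9,
                            noise_correlation = 0, n_clinical = 5,
                            seed = NULL) {
  stopifnot(n_informative >= 0, n_informative + n_clinical <= p,
            class_balance > 0, class_balance < 1, effect_size >= 0,
            conservation_coupling >= 0, conservation_coupling <= 1)
  p_mol <- p - n_clinical
  with_seed(seed, {
    n_pos <- min(m - 2L, max(2L, round(class_balance * m)))
    y <- c(rep(1L, n_pos), rep(0L, m - n_pos))
    mol_ids <- sprintf("prot%03d", seq_len(p_mol))
    clin_ids <- if (n_clinical > 0) sprintf("clin%02d", seq_len(n_clinical))
                else character(0)
    informative <- if (n_informative > 0) mol_ids[seq_len(n_informative)]
                   else character(0)
    shift <- function(eff) ifelse(y == 1L, eff / 2, -eff / 2)
    X <- matrix(stats::rnorm(m * p), m, p,
                dimnames = list(sprintf("s%03d", seq_len(m)),
                                c(mol_ids, clin_ids)))
    for (f in informative) X[, f] <- X[, f] + shift(effect_size)
    for (f in clin_ids) X[, f] <- X[, f] + shift(effect_size / 2)
    if (noise_correlation > 0) {
      pool <- setdiff(mol_ids, informative)
      spurious <- pool[seq_len(min(noise_correlation, length(pool)))]
      for (f in spurious) {
        for (try in 1:200) {
          v <- stats::rnorm(m)
          if (stats::t.test(v[y == 1], v[y == 0],
                            var.equal = TRUE)$p.value < 0.05) break
        }
        X[, f] <- v
      }
    }
    # conservation: conserved genes R ~ lognormal around 1 subst/Byr,
    # background around 8 subst/Byr (broad), mirroring left-skewed WE
    gene_ids <- paste0("gene_", mol_ids)
    conserved <- (mol_ids %in% informative) &
      (stats::runif(p_mol) < conservation_coupling)
    R <- ifelse(conserved,
                stats::rlnorm(p_mol, meanlog = log(1), sdlog = 0.3),
                stats::rlnorm(p_mol, meanlog = log(8), sdlog = 0.5))
    conservation <- data.frame(gene_id = gene_ids, L = NA_integer_,
                               L_effective = NA_integer_, R = R, WE = 1 / R)
    meta <- data.frame(
      feature_id = c(mol_ids, clin_ids),
      kind = c(rep("molecular", p_mol), rep("clinical", n_clinical)),
      gene_id = c(gene_ids, rep(NA_character_, n_clinical)))
    list(matrix = labeled_matrix(X, y), meta = meta,
         conservation = conservation,
         truth = list(informative = informative,
                      R = stats::setNames(R, mol_ids)))
  })
}
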