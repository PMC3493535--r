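# Rule-based classification of DRGs into the nine overlapping clusters:
#
#   D  - all DRGs                 DU / DD  - up- / down-regulated DRGs
#   E  - DRGs with >= 1 of: genic methylation read, promoter methylation
#        read, miRNA target, chromatin-gene (chromdb) membership
#   NE - DRGs with none of those features
#   EU / ED / NEU / NED - the four mutually exclusive leaves crossing
#        E/NE with up/down regulation.
#
# The clusters are definitional, not data-driven: membership follows
# deterministically from the feature profile and the regulation direction.

#' Classify DRGs into the nine feature/direction clusters
#'
#' Genes reported with conflicting directions across source studies are
#' kept in D (and E/NE) but excluded from DU/DD and the leaf clusters;
#' they are listed in the `conflicts` attribute. DRGs without a profile
#' row are treated as all-zero (message emitted). Non-DRG genes receive no
#' labels and do not appear in the output.
#'
#' @param drgs DRG table ([read_drg_table()]); one gene may have several
#'   rows.
#' @param profiles feature profiles ([build_feature_profiles()]).
#' @return data.frame with one row per DRG: `gene_id`, `direction`
#'   (`up`/`down`/`NA` on conflict), `epi` (`E`/`NE`), `leaf`
#'   (`EU`/`ED`/`NEU`/`NED`/`NA`); attribute `conflicts` holds the
#'   direction-conflicted gene ids.
#' @export
classify <- function(drgs, profiles) {
  bad <- !(drgs$direction %in% c("up", "down"))
  if (any(bad)) {
    stop_input("DRG direction must be 'up' or 'down' (gene ",
               drgs$gene_id[which(bad)[1L]], ")")
  }
  gid <- sort(unique(drgs$gene_id))
  dirs <- split(drgs$direction, drgs$gene_id)[gid]
  direction <- vapply(dirs, function(d) {
    u <- unique(d)
    if (length(u) == 1L) u else NA_character_
  }, "")
  conflicts <- gid[is.na(direction)]
  if (length(conflicts)) {
    message(length(conflicts),
            " DRG(s) with conflicting directions kept in D only")
  }
  m <- match(gid, profiles$gene_id)
  if (anyNA(m)) {
    message(sum(is.na(m)), " DRG(s) without a profile treated as all-zero")
  }
  has_feat <- rep(FALSE, length(gid))
  ok <- !is.na(m)
  f <- feature_flags(profiles)[m[ok], , drop = FALSE]
  has_feat[ok] <- rowSums(f) >= 1L
  epi <- ifelse(has_feat, "E", "NE")
  leaf <- ifelse(is.na(direction), NA_character_,
                 paste0(ifelse(has_feat, "E", "NE"),
                        ifelse(direction == "up", "U", "D")))
  out <- data.frame(gene_id = gid, direction = unname(direction),
                    epi = epi, leaf = leaf, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Gene ids belonging to one cluster label
#'
#' The label set is a closed enumeration (`D`, `DU`, `DD`, `E`, `NE`,
#' `EU`, `ED`, `NEU`, `NED`); anything else is an error rather than an
#' empty set.
#'
#' @param memberships output of [classify()].
#' @param label one cluster label.
#' @return character vector of gene ids.
#' @export
cluster_members <- function(memberships, label) {
  if (!(is.character(label) && length(label) == 1L &&
        label %in% CLUSTER_LABELS)) {
    stop_input("unknown cluster label: ", paste(label, collapse = ", "))
  }
  m <- memberships
  sel <- switch(label,
    D = rep(TRUE, nrow(m)),
    DU = !is.na(m$direction) & m$direction == "up",
    DD = !is.na(m$direction) & m$direction == "down",
    E = m$epi == "E",
    NE = m$epi == "NE",
    EU = !is.na(m$leaf) & m$leaf == "EU",
    ED = !is.na(m$leaf) & m$leaf == "ED",
    NEU = !is.na(m$leaf) & m$leaf == "NEU",
    NED = !is.na(m$leaf) & m$leaf == "NED"
  )
  m$gene_id[sel]
}

#' Validate the cluster partition algebra
#'
#' Checks, on a membership table, that the tree structure of the nine
#' clusters holds: DU + DD covers the direction-resolved part of D,
#' E + NE = D, EU + ED = E and NEU + NED = NE restricted to resolved
#' genes, and that sibling clusters are disjoint. Violations are reported,
#' not thrown.
#'
#' @param memberships output of [classify()] (possibly corrupted, e.g.
#'   when round-tripped through files).
#' @return data.frame of violations (`check`, `detail`); zero rows when
#'   the algebra holds.
#' @export
validate_partition <- function(memberships) {
  sets <- setNames(lapply(CLUSTER_LABELS, cluster_members,
                          memberships = memberships), CLUSTER_LABELS)
  resolved <- memberships$gene_id[!is.na(memberships$direction)]
  viol <- list()
  note <- function(check, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(check = check, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  pair_disjoint <- function(a, b) {
    both <- intersect(sets[[a]], sets[[b]])
    if (length(both)) {
      note(paste0(a, " disjoint ", b),
           paste("genes in both:", paste(both, collapse = ",")))
    }
  }
  sum_check <- function(parts, whole, label) {
    u <- unique(unlist(sets[parts], use.names = FALSE))
    if (!setequal(u, whole) ||
        sum(lengths(sets[parts])) != length(whole)) {
      note(label, sprintf("sum %d vs expected %d",
                          sum(lengths(sets[parts])), length(whole)))
    }
  }
  sum_check(c("DU", "DD"), resolved, "n(DU)+n(DD)=n(D resolved)")
  sum_check(c("E", "NE"), sets$D, "n(E)+n(NE)=n(D)")
  sum_check(c("EU", "ED"), intersect(sets$E, resolved),
            "n(EU)+n(ED)=n(E resolved)")
  sum_check(c("NEU", "NED"), intersect(sets$NE, resolved),
            "n(NEU)+n(NED)=n(NE resolved)")
  pair_disjoint("DU", "DD")
  pair_disjoint("E", "NE")
  for (p in utils::combn(c("EU", "ED", "NEU", "NED"), 2,
                         simplify = FALSE)) {
    pair_disjoint(p[1], p[2])
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), detail = character())
}

#' Per-gene absolute fold change
#'
#' Genes reported by several source studies are reduced to one value per
#' gene: the maximum absolute fold change by default, configurable to the
#' mean.
#'
#' @param drgs DRG table.
#' @param reduce `"max"` or `"mean"`.
#' @return named numeric vector keyed by gene id.
#' @export
gene_fold_change <- function(drgs, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  f <- switch(reduce, max = max, mean = mean)
  out <- tapply(abs(drgs$fold_change), drgs$gene_id, f)
  setNames(as.numeric(out), names(out))
}

#' Per-cluster fold-change summary
#'
#' Mean absolute fold change and size for each of the nine clusters, plus
#' each cluster's share of its parent in the tree (D is its own parent).
#' Empty clusters get `NA` means, never 0.
#'
#' @param memberships output of [classify()].
#' @param drgs DRG table.
#' @param reduce per-gene reduction passed to [gene_fold_change()].
#' @return data.frame with columns `cluster`, `n_genes`,
#'   `mean_abs_fold_change`, `percent_of_parent`.
#' @export
fold_change_summary <- function(memberships, drgs,
                                reduce = c("max", "mean")) {
  fc <- gene_fold_change(drgs, reduce)
  if (!all(memberships$gene_id %in% names(fc))) {
    stop_input("membership gene(s) missing from the DRG table")
  }
  parent <- c(D = "D", DU = "D", DD = "D", E = "D", NE = "D",
              EU = "E", ED = "E", NEU = "NE", NED = "NE")
  sets <- setNames(lapply(CLUSTER_LABELS, cluster_members,
                          memberships = memberships), CLUSTER_LABELS)
  rows <- lapply(CLUSTER_LABELS, function(lab) {
    ids <- sets[[lab]]
    data.frame(
      cluster = lab, n_genes = length(ids),
      mean_abs_fold_change = if (length(ids)) mean(fc[ids]) else NA_real_,
      percent_of_parent = pct(length(ids), length(sets[[parent[lab]]]), 1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
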