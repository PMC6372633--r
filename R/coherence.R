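# Genotype-metabotype coherence: cluster plants into as many metabotype
# clusters as there are genotypes and ask, per genotype, whether all of its
# replicates land in one cluster that contains no other genotype's plants.

#' Genotype x cluster contingency table
#'
#' @param cluster_labels integer/character cluster label per plant.
#' @param genotype_labels genotype per plant, same length.
#' @return a `coherence_table`: `counts` (genotype x cluster matrix),
#'   `occupied` (clusters occupied per genotype).
#' @export
build_coherence_table <- function(cluster_labels, genotype_labels) {
  if (length(cluster_labels) != length(genotype_labels))
    stop("cluster and genotype label vectors differ in length")
  counts <- table(genotype = genotype_labels, cluster = cluster_labels)
  counts <- matrix(counts, nrow = nrow(counts), dimnames = dimnames(counts))
  structure(list(counts = counts,
                 occupied = rowSums(counts > 0)),
            class = "coherence_table")
}

#' Coherence fraction and coherent-genotype list
#'
#' A genotype is coherent iff all of its plants share one cluster and (with
#' `require_purity = TRUE`, the default) no other genotype's plant occupies
#' that cluster. The unanimity-only variant is available via
#' `require_purity = FALSE`.
#'
#' @param table a [build_coherence_table()] result.
#' @param require_purity demand that the shared cluster is private to the
#'   genotype.
#' @return list with `fraction`, `coherent` (genotype names) and the rule
#'   used.
#' @export
coherence_fraction <- function(table, require_purity = TRUE) {
  stopifnot(inherits(table, "coherence_table"))
  counts <- table$counts
  coherent <- character(0)
  for (g in rownames(counts)) {
    occ <- which(counts[g, ] > 0)
    if (length(occ) != 1L) next
    if (require_purity && sum(counts[, occ] > 0) > 1L) next
    coherent <- c(coherent, g)
  }
  list(fraction = length(coherent) / nrow(counts), coherent = coherent,
       rule = if (require_purity) "unanimity+purity" else "unanimity")
}

#' Tidy bubble-plot data
#'
#' @param table a [build_coherence_table()] result.
#' @return data.frame `genotype, cluster, n_plants` (nonzero cells only).
#' @export
coherence_bubble_data <- function(table) {
  stopifnot(inherits(table, "coherence_table"))
  idx <- which(table$counts > 0, arr.ind = TRUE)
  data.frame(genotype = rownames(table$counts)[idx[, 1]],
             cluster = colnames(table$counts)[idx[, 2]],
             n_plants = table$counts[idx])
}
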