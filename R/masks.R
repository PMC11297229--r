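#' Sparse connectivity mask between two named layers
#'
#' A `connectivity_mask` records the binary wiring of one network layer:
#' an ordered list of input unit names, an ordered list of output unit
#' names, and the set of (input, output) edges. Edges are stored in a
#' canonical column-major order (by output index, then input index), the
#' same order in which the corresponding weight vector is laid out in a
#' trained model.
#'
#' @param in_ids character vector of input unit names (unique).
#' @param out_ids character vector of output unit names (unique).
#' @param in_idx integer vector of edge input indices (1-based).
#' @param out_idx integer vector of edge output indices (1-based).
#' @param tags optional character vector, one per edge, labelling the
#'   source omic ("me", "ge", "covariate", ...) for omic-specific
#'   penalties and contribution splits.
#' @return an object of class `connectivity_mask`.
#' @export
connectivity_mask <- function(in_ids, out_ids, in_idx, out_idx, tags = NULL) {
  in_ids <- as.character(in_ids)
  out_ids <- as.character(out_ids)
  in_idx <- as.integer(in_idx)
  out_idx <- as.integer(out_idx)
  if (anyDuplicated(in_ids)) stop("duplicate input unit names in mask")
  if (anyDuplicated(out_ids)) stop("duplicate output unit names in mask")
  if (length(in_idx) != length(out_idx)) stop("in_idx and out_idx lengths differ")
  if (length(in_idx) > 0) {
    if (min(in_idx) < 1L || max(in_idx) > length(in_ids)) {
      stop("edge input index out of range")
    }
    if (min(out_idx) < 1L || max(out_idx) > length(out_ids)) {
      stop("edge output index out of range")
    }
  }
  key <- (out_idx - 1) * length(in_ids) + in_idx
  if (anyDuplicated(key)) stop("duplicate edges in mask")
  ord <- order(out_idx, in_idx)
  if (!is.null(tags)) {
    if (length(tags) != length(in_idx)) stop("tags length must equal edge count")
    tags <- as.character(tags)[ord]
  }
  structure(
    list(
      in_ids = in_ids, out_ids = out_ids,
      in_idx = in_idx[ord], out_idx = out_idx[ord],
      tags = tags
    ),
    class = "connectivity_mask"
  )
}

#' Number of edges in a connectivity mask
#' @param mask a `connectivity_mask`.
#' @return integer edge count.
#' @export
n_edges <- function(mask) length(mask$in_idx)

#' @export
print.connectivity_mask <- function(x, ...) {
  cat(sprintf(
    "connectivity_mask: %d inputs -> %d outputs, %d edges%s\n",
    length(x$in_ids), length(x$out_ids), n_edges(x),
    if (is.null(x$tags)) "" else sprintf(" (tags: %s)", paste(unique(x$tags), collapse = ","))
  ))
  invisible(x)
}

#' Realize a mask as a sparse weight matrix
#'
#' Builds an `n_in x n_out` `dgCMatrix` whose nonzeros sit exactly on the
#' mask edges. Because mask edges are stored in canonical column-major
#' order, the matrix `@x` slot aligns one-to-one with a weight vector in
#' mask-edge order.
#'
#' @param mask a `connectivity_mask`.
#' @param x numeric weights, one per edge (default all 1).
#' @return a `Matrix::dgCMatrix`.
#' @export
mask_matrix <- function(mask, x = rep(1, n_edges(mask))) {
  if (length(x) != n_edges(mask)) stop("weight vector length must equal edge count")
  Matrix::sparseMatrix(
    i = mask$in_idx, j = mask$out_idx, x = as.numeric(x),
    dims = c(length(mask$in_ids), length(mask$out_ids)),
    dimnames = list(mask$in_ids, mask$out_ids)
  )
}

#' Assign each CpG site to its nearest gene
#'
#' Each CpG is connected to the gene whose transcription start site (TSS)
#' is closest in base pairs on the same chromosome. Ties are broken
#' deterministically towards the smaller TSS coordinate, then the
#' lexicographically smaller gene id. CpGs on chromosomes without any
#' gene are dropped (and reported in the `dropped` element).
#'
#' @param cpgs data.frame with columns `cpg_id`, `chrom`, `pos`
#'   (1-based bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based bp) and optionally `strand`.
#' @param max_distance optional maximum CpG-TSS distance in bp; CpGs
#'   farther than this from every gene are dropped. Default `Inf`
#'   (no cutoff).
#' @return list with `pairs` (named character, cpg_id -> gene_id),
#'   `distance` (named integer, bp) and `dropped` (character vector of
#'   unassigned cpg ids).
#' @export
map_cpgs_to_genes <- function(cpgs, genes, max_distance = Inf) {
  cpgs <- as.data.frame(cpgs)
  genes <- as.data.frame(genes)
  need_c <- c("cpg_id", "chrom", "pos")
  need_g <- c("gene_id", "chrom", "tss")
  if (!all(need_c %in% names(cpgs))) stop("cpgs must have columns cpg_id, chrom, pos")
  if (!all(need_g %in% names(genes))) stop("genes must have columns gene_id, chrom, tss")
  if (nrow(genes) == 0) stop("gene table is empty: cannot annotate CpGs")
  if (anyDuplicated(cpgs$cpg_id)) stop("duplicate cpg_id in CpG table")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  bad_c <- which(!is.finite(cpgs$pos) | cpgs$pos < 1)
  if (length(bad_c)) {
    stop(sprintf("malformed CpG coordinate at row %d (cpg_id %s)", bad_c[1], cpgs$cpg_id[bad_c[1]]))
  }
  bad_g <- which(!is.finite(genes$tss) | genes$tss < 1)
  if (length(bad_g)) {
    stop(sprintf("malformed gene coordinate at row %d (gene_id %s)", bad_g[1], genes$gene_id[bad_g[1]]))
  }

  assigned_gene <- rep(NA_character_, nrow(cpgs))
  assigned_dist <- rep(NA_integer_, nrow(cpgs))

  for (chr in unique(cpgs$chrom)) {
    ci <- which(cpgs$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    tss <- g$tss
    pos <- cpgs$pos[ci]
    k <- findInterval(pos, tss)           # index of last tss <= pos (0 if none)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(tss))
    dl <- ifelse(k >= 1L, pos - tss[left], Inf)
    dr <- ifelse(k < length(tss), tss[right] - pos, Inf)
    pick <- ifelse(dl <= dr, left, right)  # tie -> smaller tss
    dist <- pmin(dl, dr)
    # within identical tss values prefer the lexicographically smallest id:
    # rows are sorted by (tss, gene_id), so remap to the first row of the run
    first_of_tss <- match(tss[pick], tss)
    assigned_gene[ci] <- g$gene_id[first_of_tss]
    assigned_dist[ci] <- as.integer(dist)
  }

  if (is.finite(max_distance)) {
    too_far <- !is.na(assigned_dist) & assigned_dist > max_distance
    assigned_gene[too_far] <- NA_character_
    assigned_dist[too_far] <- NA_integer_
  }
  keep <- !is.na(assigned_gene)
  pairs <- stats::setNames(assigned_gene[keep], cpgs$cpg_id[keep])
  distance <- stats::setNames(assigned_dist[keep], cpgs$cpg_id[keep])
  dropped <- cpgs$cpg_id[!keep]
  if (length(dropped)) {
    message(sprintf("map_cpgs_to_genes: dropped %d CpG(s) with no gene in range", length(dropped)))
  }
  list(pairs = pairs, distance = distance, dropped = dropped)
}

#' Intersect the gene universes of two omics
#'
#' Returns the sorted intersection of the genes measured by methylation
#' (via CpG annotation) and by expression. The sorted order is the
#' canonical gene-node order used by every downstream mask, weight vector
#' and report.
#'
#' @param me_genes character vector of genes reachable from methylation.
#' @param ge_genes character vector of genes with expression data.
#' @return sorted character vector of shared genes.
#' @export
intersect_gene_sets <- function(me_genes, ge_genes) {
  if (length(me_genes) == 0 || length(ge_genes) == 0) {
    stop("gene sets must be nonempty")
  }
  shared <- sort(intersect(unique(as.character(me_genes)), unique(as.character(ge_genes))))
  if (length(shared) == 0) stop("no genes shared between the two omics")
  shared
}

#' Build the CpG-to-gene connectivity mask
#'
#' One edge per CpG, from the CpG input unit to the gene node it is
#' annotated to. CpGs whose gene is not in `gene_order` are dropped (the
#' count and ids are attached as attributes); genes without any CpG are
#' flagged.
#'
#' @param map result of [map_cpgs_to_genes()].
#' @param gene_order character vector defining gene-node order
#'   (typically from [intersect_gene_sets()]).
#' @param cpg_order character vector of CpG ids defining input order.
#' @return a `connectivity_mask` (in = retained CpGs, out = genes) with
#'   attributes `dropped_cpgs` and `empty_genes`.
#' @export
build_gene_mask <- function(map, gene_order, cpg_order) {
  gene_order <- as.character(gene_order)
  cpg_order <- as.character(cpg_order)
  miss <- setdiff(cpg_order, names(map$pairs))
  if (length(miss)) {
    stop(sprintf("%d CpG(s) in cpg_order missing from the CpG-gene map (first: %s)",
                 length(miss), miss[1]))
  }
  g <- map$pairs[cpg_order]
  j <- match(g, gene_order)
  keep <- !is.na(j)
  dropped <- cpg_order[!keep]
  if (length(dropped)) {
    message(sprintf("build_gene_mask: excluded %d CpG(s) mapping outside the gene order",
                    length(dropped)))
  }
  in_ids <- cpg_order[keep]
  mask <- connectivity_mask(
    in_ids = in_ids, out_ids = gene_order,
    in_idx = seq_along(in_ids), out_idx = j[keep],
    tags = rep("me", length(in_ids))
  )
  empty <- setdiff(gene_order, g[keep])
  attr(mask, "dropped_cpgs") <- dropped
  attr(mask, "empty_genes") <- empty
  mask
}

#' Build the pathway-hierarchy masks and the skip mask
#'
#' Converts a three-level pathway hierarchy (local -> mid -> global) into
#' the masks of the pathway layers: gene to local pathway (following
#' membership, multi-membership allowed), local to mid and mid to global
#' (following the parent map), plus a skip mask with one edge per gene
#' that belongs to no local pathway, wired straight to the output node.
#' Pathways with no member gene after restriction to `gene_order` are
#' dropped with a warning.
#'
#' @param hierarchy list with `membership` (named list, gene_id ->
#'   character vector of local pathway ids) and `parent` (named character,
#'   child pathway id -> parent pathway id, covering local->mid and
#'   mid->global).
#' @param gene_order character vector of gene node names.
#' @return list with masks `gene_local`, `local_mid`, `mid_global`,
#'   `skip` and character vectors `annotated_genes`, `skip_genes`.
#' @export
build_pathway_masks <- function(hierarchy, gene_order) {
  gene_order <- as.character(gene_order)
  membership <- hierarchy$membership
  parent <- hierarchy$parent
  mem <- membership[intersect(names(membership), gene_order)]
  mem <- mem[vapply(mem, length, 1L) > 0]

  g_idx <- rep(match(names(mem), gene_order), times = vapply(mem, length, 1L))
  locals_all <- unlist(mem, use.names = FALSE)
  local_ids <- sort(unique(locals_all))
  orphan <- setdiff(unique(unlist(membership, use.names = FALSE)), local_ids)
  if (length(orphan)) {
    warning(sprintf("dropped %d local pathway(s) with no member gene in gene_order", length(orphan)))
  }
  if (length(local_ids) == 0) {
    stop("no pathway has any member gene in gene_order")
  }
  gene_local <- connectivity_mask(
    in_ids = gene_order, out_ids = local_ids,
    in_idx = g_idx, out_idx = match(locals_all, local_ids)
  )

  mid_of_local <- unname(parent[local_ids])
  if (anyNA(mid_of_local)) {
    stop(sprintf("local pathway %s has no parent in the hierarchy",
                 local_ids[which(is.na(mid_of_local))[1]]))
  }
  mid_ids <- sort(unique(mid_of_local))
  local_mid <- connectivity_mask(
    in_ids = local_ids, out_ids = mid_ids,
    in_idx = seq_along(local_ids), out_idx = match(mid_of_local, mid_ids)
  )

  global_of_mid <- unname(parent[mid_ids])
  if (anyNA(global_of_mid)) {
    stop(sprintf("mid pathway %s has no parent in the hierarchy",
                 mid_ids[which(is.na(global_of_mid))[1]]))
  }
  global_ids <- sort(unique(global_of_mid))
  mid_global <- connectivity_mask(
    in_ids = mid_ids, out_ids = global_ids,
    in_idx = seq_along(mid_ids), out_idx = match(global_of_mid, global_ids)
  )

  annotated <- names(mem)
  skip_genes <- setdiff(gene_order, annotated)
  skip <- connectivity_mask(
    in_ids = skip_genes, out_ids = "y",
    in_idx = seq_along(skip_genes),
    out_idx = rep(1L, length(skip_genes))
  )
  list(
    gene_local = gene_local, local_mid = local_mid, mid_global = mid_global,
    skip = skip,
    annotated_genes = sort(annotated), skip_genes = skip_genes
  )
}

#' Write a connectivity mask to a JSON container
#'
#' Serializes id lists and the coordinate edge list; round-trips
#' bit-exactly through [read_mask()].
#'
#' @param mask a `connectivity_mask`.
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  obj <- list(
    format = "vnnomics_mask", version = 1L,
    in_ids = mask$in_ids, out_ids = mask$out_ids,
    in_idx = mask$in_idx, out_idx = mask$out_idx
  )
  if (!is.null(mask$tags)) obj$tags <- mask$tags
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity mask from its JSON container
#' @param path file written by [write_mask()].
#' @return a `connectivity_mask`.
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vnnomics_mask")) stop("not a vnnomics mask file: ", path)
  connectivity_mask(obj$in_ids, obj$out_ids, obj$in_idx, obj$out_idx, tags = obj$tags)
}
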