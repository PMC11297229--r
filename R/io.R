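guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample-by-feature matrix from TSV/CSV
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' With `orientation = "features_rows"` the file holds the transposed
#' layout (features in rows) and is transposed on read. Duplicate ids
#' and missing values are errors: the method assumes complete data.
#'
#' @param path TSV (default) or CSV file.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @return numeric matrix, rows = samples, columns = features.
#' @export
read_matrix <- function(path, orientation = c("samples_rows", "features_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row id '%s' in %s", ids[anyDuplicated(ids)], path))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop(sprintf("duplicate column id '%s' in %s",
                 names(df)[-1][anyDuplicated(names(df)[-1])], path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row '%s', column '%s' in %s",
                 rownames(m)[idx[1]], colnames(m)[idx[2]], path))
  }
  if (orientation == "features_rows") m <- t(m)
  m
}

#' Write a sample-by-feature matrix to TSV/CSV
#'
#' Inverse of [read_matrix()]; the first column holds the sample ids.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path (`.csv` switches to comma separation).
#' @param id_col name of the id column header (default "sample_id").
#' @export
write_matrix <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pathway membership from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Pathways with no genes
#' are dropped with a warning.
#'
#' @param path GMT file.
#' @return named list, pathway id -> character vector of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning(sprintf("pathway '%s' has no genes; dropped", parts[1]))
      next
    }
    out[[parts[1]]] <- genes
  }
  out
}

#' Write pathway membership to a GMT file
#' @param pathways named list, pathway id -> gene ids.
#' @param path output path.
#' @param descriptions optional named descriptions (default "na").
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(p) {
    d <- descriptions[[p]] %||% "na"
    paste(c(p, d, pathways[[p]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a pathway membership list to a gene-centric map
#'
#' @param pathways named list, pathway -> genes (e.g. from
#'   [read_gmt()]).
#' @return named list, gene -> character vector of pathway ids, as the
#'   `membership` element of a hierarchy.
#' @export
pathways_to_membership <- function(pathways) {
  genes <- unique(unlist(pathways, use.names = FALSE))
  pw_of <- stats::setNames(vector("list", length(genes)), genes)
  for (p in names(pathways)) {
    for (g in pathways[[p]]) pw_of[[g]] <- c(pw_of[[g]], p)
  }
  pw_of
}

#' Read a child-parent pathway hierarchy table
#'
#' Two-column TSV/CSV (`child`, `parent`) covering local-to-mid and
#' mid-to-global links.
#'
#' @param path file path.
#' @return named character vector, child -> parent.
#' @export
read_hierarchy_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("hierarchy table needs columns child, parent")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a CpG position table
#'
#' CSV/TSV with columns `cpg_id`, `chrom`, `pos` (1-based), or BED-like
#' columns `chrom`, `start`, `end`, `name` (0-based half-open; the
#' position is taken as `start + 1`).
#'
#' @param path file path.
#' @return data.frame with columns `cpg_id`, `chrom`, `pos`.
#' @export
read_cpg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          stringsAsFactors = FALSE)
  if (all(c("cpg_id", "chrom", "pos") %in% names(df))) {
    df[, c("cpg_id", "chrom", "pos")]
  } else if (all(c("chrom", "start", "name") %in% names(df))) {
    data.frame(cpg_id = df$name, chrom = df$chrom, pos = df$start + 1L,
               stringsAsFactors = FALSE)
  } else {
    stop("CpG table needs columns (cpg_id, chrom, pos) or BED-like (chrom, start, end, name)")
  }
}

#' Read a gene region table
#'
#' CSV/TSV with columns `gene_id`, `chrom`, `tss` (1-based) and
#' optional `strand`, or BED-like `chrom`, `start`, `end`, `name`,
#' (`strand`) with 0-based half-open coordinates: the TSS is `start + 1`
#' on the + strand and `end` on the - strand.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          stringsAsFactors = FALSE)
  if (all(c("gene_id", "chrom", "tss") %in% names(df))) {
    df$strand <- df$strand %||% "+"
    df[, c("gene_id", "chrom", "tss", "strand")]
  } else if (all(c("chrom", "start", "end", "name") %in% names(df))) {
    strand <- df$strand %||% rep("+", nrow(df))
    data.frame(
      gene_id = df$name, chrom = df$chrom,
      tss = ifelse(strand == "-", df$end, df$start + 1L),
      strand = strand, stringsAsFactors = FALSE
    )
  } else {
    stop("gene table needs columns (gene_id, chrom, tss) or BED-like (chrom, start, end, name)")
  }
}

#' Inner-join omics matrices and phenotypes on sample id
#'
#' Keeps the samples present in all sources (complete multi-omics
#' cases); counts of dropped samples per source are attached as the
#' `dropped` attribute.
#'
#' @param me sample-by-CpG matrix with rownames.
#' @param ge sample-by-gene matrix with rownames.
#' @param phenotypes data.frame with a `sample_id` column plus phenotype
#'   / covariate / cohort columns.
#' @param phenotype_col name of the outcome column (default
#'   "phenotype").
#' @param cohort_col name of the cohort column (default "cohort").
#' @param covariate_cols optional character vector of covariate columns.
#' @return an `omics_dataset` restricted to the shared samples.
#' @export
align_samples <- function(me, ge, phenotypes, phenotype_col = "phenotype",
                          cohort_col = "cohort", covariate_cols = NULL) {
  ids <- Reduce(intersect, list(rownames(me), rownames(ge),
                                as.character(phenotypes$sample_id)))
  if (length(ids) == 0) stop("no samples shared between methylation, expression and phenotypes")
  dropped <- list(
    me = setdiff(rownames(me), ids),
    ge = setdiff(rownames(ge), ids),
    phenotypes = setdiff(as.character(phenotypes$sample_id), ids)
  )
  n_drop <- vapply(dropped, length, 0L)
  if (any(n_drop > 0)) {
    message(sprintf("align_samples: dropped %d (me), %d (ge), %d (phenotype) unmatched sample(s)",
                    n_drop[["me"]], n_drop[["ge"]], n_drop[["phenotypes"]]))
  }
  ph <- phenotypes[match(ids, as.character(phenotypes$sample_id)), , drop = FALSE]
  covariates <- NULL
  if (!is.null(covariate_cols)) {
    covariates <- ph[, covariate_cols, drop = FALSE]
    rownames(covariates) <- ids
  }
  ds <- omics_dataset(
    me = me[ids, , drop = FALSE], ge = ge[ids, , drop = FALSE],
    phenotype = ph[[phenotype_col]], cohort = ph[[cohort_col]],
    covariates = covariates
  )
  attr(ds, "dropped") <- dropped
  ds
}

#' Filter expression genes by average counts per million
#'
#' Keeps genes whose mean CPM across samples is at least `min_cpm`
#' (default 1), the standard inclusion rule for RNA-seq count matrices.
#'
#' @param ge sample-by-gene count matrix.
#' @param min_cpm minimum average CPM (default 1).
#' @return the filtered matrix; removed genes in attribute `removed`.
#' @export
filter_expression_cpm <- function(ge, min_cpm = 1) {
  lib <- rowSums(ge)
  cpm <- sweep(ge, 1, lib, `/`) * 1e6
  keep <- colMeans(cpm) >= min_cpm
  out <- ge[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(ge)[!keep]
  out
}

#' Write a dataset with annotations to interchange files
#'
#' Emits the formats the package's readers consume: TSV matrices
#' (`methylation.tsv`, `expression.tsv`), a CSV phenotype table
#' (`phenotypes.csv` with sample id, phenotype, cohort, covariates),
#' CSV annotation tables (`cpgs.csv`, `genes.csv`), and, when a
#' simulation truth is given, a JSON ground-truth manifest
#' (`truth.json`).
#'
#' @param sim result of [simulate_omics()] /
#'   [simulate_classification()], or a list with at least `dataset`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  paths <- c(
    me = file.path(dir, "methylation.tsv"),
    ge = file.path(dir, "expression.tsv"),
    ph = file.path(dir, "phenotypes.csv")
  )
  write_matrix(ds$me, paths[["me"]])
  write_matrix(ds$ge, paths[["ge"]])
  ph <- data.frame(sample_id = ds$sample_ids, phenotype = ds$phenotype,
                   cohort = ds$cohort, stringsAsFactors = FALSE)
  if (!is.null(ds$covariates)) ph <- cbind(ph, ds$covariates)
  utils::write.table(ph, paths[["ph"]], sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$annotations)) {
    paths[["cpgs"]] <- file.path(dir, "cpgs.csv")
    paths[["genes"]] <- file.path(dir, "genes.csv")
    utils::write.table(sim$annotations$cpgs, paths[["cpgs"]], sep = ",",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$annotations$genes, paths[["genes"]], sep = ",",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    truth <- sim$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#' @param dir directory containing the interchange files.
#' @return an `omics_dataset`.
#' @export
read_dataset <- function(dir) {
  me <- read_matrix(file.path(dir, "methylation.tsv"))
  ge <- read_matrix(file.path(dir, "expression.tsv"))
  ph <- utils::read.table(file.path(dir, "phenotypes.csv"), header = TRUE,
                          sep = ",", stringsAsFactors = FALSE)
  cov_cols <- setdiff(names(ph), c("sample_id", "phenotype", "cohort"))
  align_samples(me, ge, ph,
                covariate_cols = if (length(cov_cols)) cov_cols else NULL)
}

#' Serialize a network spec and trained model to one JSON container
#'
#' Stores the layer definitions (with masks as coordinate lists),
#' weights, biases, seed and task; round-trips through [read_model()]
#' bit-exactly for ids and to full double precision for values.
#'
#' @param state a `vnn_model`.
#' @param spec the matching `network_spec`.
#' @param path output file.
#' @export
write_model <- function(state, spec, path) {
  layers <- lapply(seq_along(spec$layers), function(k) {
    layer <- spec$layers[[k]]
    st <- state$layers[[k]]
    base <- list(name = layer$name, kind = layer$kind,
                 activation = layer$activation, l1 = isTRUE(layer$l1),
                 b = st$b)
    if (layer$kind == "masked") {
      m <- layer$mask
      c(base, list(in_ids = m$in_ids, out_ids = m$out_ids,
                   in_idx = m$in_idx, out_idx = m$out_idx,
                   tags = m$tags, W = st$W))
    } else {
      c(base, list(in_ids = layer$in_ids, width = layer$width,
                   W = as.vector(st$W)))
    }
  })
  obj <- list(
    format = "vnnomics_model", version = 1L,
    task = spec$task,
    input_blocks = spec$input_blocks,
    gene_layer = spec$gene_layer,
    gene_order = spec$gene_order,
    meta = state$meta[c("seed", "y_mean", "best_epoch")],
    layers = layers
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model container written by [write_model()]
#' @param path JSON file.
#' @return list with `spec` (a `network_spec`) and `state` (a
#'   `vnn_model`).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$format, "vnnomics_model")) stop("not a vnnomics model file: ", path)
  layers <- list()
  states <- list()
  raw_layers <- obj$layers
  for (k in seq_along(raw_layers)) {
    rl <- raw_layers[[k]]
    if (rl$kind == "masked") {
      mask <- connectivity_mask(rl$in_ids, rl$out_ids, rl$in_idx, rl$out_idx,
                                tags = rl$tags)
      layers[[k]] <- new_masked_layer(rl$name, mask, rl$activation, isTRUE(rl$l1))
      states[[k]] <- list(W = as.numeric(rl$W), b = as.numeric(rl$b))
    } else {
      layers[[k]] <- new_dense_layer(rl$name, rl$in_ids, rl$width,
                                     rl$activation, isTRUE(rl$l1))
      states[[k]] <- list(
        W = matrix(as.numeric(rl$W), length(rl$in_ids), rl$width),
        b = as.numeric(rl$b)
      )
    }
  }
  input_blocks <- lapply(obj$input_blocks, as.character)
  spec <- new_network_spec(layers, obj$task, input_blocks,
                           gene_layer = obj$gene_layer,
                           gene_order = obj$gene_order)
  state <- structure(list(layers = states, meta = as.list(obj$meta)),
                     class = "vnn_model")
  list(spec = spec, state = state)
}
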