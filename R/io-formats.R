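#' Construct an omics cohort bundle
#'
#' Bundles one cancer type's omics layers with aligned sample identifiers.
#' Expression is mandatory; CNV, methylation, mutations and clinical data
#' are optional. Samples present in an optional layer but absent from the
#' expression columns are reported as orphans via a warning.
#'
#' @param cancer_code Short cohort label.
#' @param expression Numeric genes x samples matrix of log2 expression with
#'   row and column names.
#' @param sample_type Named character vector (sample -> "tumor"/"normal")
#'   covering every expression column.
#' @param cnv Optional genes x tumor-samples numeric matrix.
#' @param methylation Optional genes x samples beta-value matrix in \[0, 1\].
#' @param mutations Optional MAF-style data frame (see [read_maf()]).
#' @param clinical Optional data frame with columns `sample`, `os_time`,
#'   `os_event` and optionally `t_index`, `n_index`, `m_index`, `stage`,
#'   `gender`, `age`.
#' @return An object of class `omics_cohort`.
#' @export
new_omics_cohort <- function(cancer_code, expression, sample_type,
                             cnv = NULL, methylation = NULL,
                             mutations = NULL, clinical = NULL) {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression)))
    stop("expression must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample identifiers in expression columns", call. = FALSE)
  if (anyDuplicated(rownames(expression)))
    stop("duplicate gene identifiers in expression rows", call. = FALSE)
  missing_type <- setdiff(colnames(expression), names(sample_type))
  if (length(missing_type))
    stop("samples without tumor/normal label: ",
         paste(utils::head(missing_type, 5), collapse = ", "), call. = FALSE)
  if (!all(sample_type %in% c("tumor", "normal")))
    stop("sample_type values must be 'tumor' or 'normal'", call. = FALSE)

  check_orphans <- function(ids, layer) {
    orphans <- setdiff(ids, colnames(expression))
    if (length(orphans))
      warning(sprintf("%s: %d orphan sample(s) not in expression columns (e.g. %s)",
                      layer, length(orphans), orphans[1]), call. = FALSE)
  }
  if (!is.null(cnv)) check_orphans(colnames(cnv), "cnv")
  if (!is.null(methylation)) {
    check_orphans(colnames(methylation), "methylation")
    bad <- which(methylation < 0 | methylation > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("methylation beta out of [0,1] for gene %s, sample %s",
                   rownames(methylation)[bad[1, 1]],
                   colnames(methylation)[bad[1, 2]]), call. = FALSE)
  }
  if (!is.null(clinical)) {
    check_orphans(clinical$sample, "clinical")
    if (any(clinical$os_time < 0, na.rm = TRUE))
      stop("negative survival times in clinical table", call. = FALSE)
    if (!all(clinical$os_event %in% c(0, 1, NA)))
      stop("os_event must be 0/1", call. = FALSE)
  }
  structure(list(cancer_code = cancer_code, expression = expression,
                 sample_type = sample_type, cnv = cnv,
                 methylation = methylation, mutations = mutations,
                 clinical = clinical),
            class = "omics_cohort")
}

#' @export
print.omics_cohort <- function(x, ...) {
  st <- table(x$sample_type[colnames(x$expression)])
  cat(sprintf("omics_cohort '%s': %d genes, %d tumor / %d normal samples\n",
              x$cancer_code, nrow(x$expression),
              st[["tumor"]], if ("normal" %in% names(st)) st[["normal"]] else 0L))
  cat(sprintf("  layers: expression%s%s%s%s\n",
              if (!is.null(x$cnv)) ", cnv" else "",
              if (!is.null(x$methylation)) ", methylation" else "",
              if (!is.null(x$mutations)) ", mutations" else "",
              if (!is.null(x$clinical)) ", clinical" else ""))
  invisible(x)
}

#' Tumor and normal sample identifiers of a cohort
#' @param cohort An `omics_cohort`.
#' @return Character vector of sample ids.
#' @export
tumor_samples <- function(cohort) {
  names(cohort$sample_type)[cohort$sample_type == "tumor"]
}

#' @rdname tumor_samples
#' @export
normal_samples <- function(cohort) {
  names(cohort$sample_type)[cohort$sample_type == "normal"]
}

# ---- flat-file dialect -------------------------------------------------
# matrices: first column = gene id, header row = sample ids, tab-separated;
# missing values written as "NA"; floats at 15 significant digits so a
# write -> read round trip is lossless well beyond 12 digits.

.write_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.read_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  ragged <- which(vapply(fields, length, integer(1)) != ncol_expect)
  if (length(ragged))
    stop(sprintf("parse error in %s: ragged row at line %d", path, ragged[1]),
         call. = FALSE)
  header <- fields[[1]][-1]
  genes <- vapply(fields[-1], `[[`, character(1), 1L)
  dup <- which(duplicated(genes))
  if (length(dup))
    stop(sprintf("parse error in %s: duplicate gene id '%s' at line %d",
                 path, genes[dup[1]], dup[1] + 1L), call. = FALSE)
  vals <- vapply(fields[-1], function(f) {
    suppressWarnings(as.numeric(ifelse(f[-1] == "" | f[-1] == "NA", NA, f[-1])))
  }, numeric(ncol_expect - 1L))
  m <- t(matrix(vals, nrow = ncol_expect - 1L))
  dimnames(m) <- list(genes, header)
  m
}

#' Read and write MAF-style mutation tables
#'
#' A minimal MAF dialect with the columns the mutation module needs:
#' Hugo_Symbol, Tumor_Sample_Barcode, Variant_Classification, Variant_Type,
#' Reference_Allele, Tumor_Seq_Allele2. Extra columns are preserved on read.
#'
#' @param path File path.
#' @return `read_maf`: a data frame of mutation records.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
            "Variant_Type", "Reference_Allele", "Tumor_Seq_Allele2")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("MAF file missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_maf
#' @param records Data frame of mutation records.
#' @export
write_maf <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Writes expression/CNV/methylation as tab-separated genes x samples
#' matrices, mutations as MAF, and sample types plus clinical data as
#' tab-separated tables, using file names `read_cohort()` expects.
#'
#' @param cohort An `omics_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             sample_type = file.path(dir, "sample_type.tsv"))
  .write_matrix(cohort$expression, paths[["expression"]])
  utils::write.table(
    data.frame(sample = names(cohort$sample_type),
               type = unname(cohort$sample_type), stringsAsFactors = FALSE),
    paths[["sample_type"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$cnv)) {
    paths[["cnv"]] <- file.path(dir, "cnv.tsv")
    .write_matrix(cohort$cnv, paths[["cnv"]])
  }
  if (!is.null(cohort$methylation)) {
    paths[["methylation"]] <- file.path(dir, "methylation.tsv")
    .write_matrix(cohort$methylation, paths[["methylation"]])
  }
  if (!is.null(cohort$mutations)) {
    paths[["mutations"]] <- file.path(dir, "mutations.maf")
    write_maf(cohort$mutations, paths[["mutations"]])
  }
  if (!is.null(cohort$clinical)) {
    paths[["clinical"]] <- file.path(dir, "clinical.tsv")
    utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(paths)
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled files
#'   in the same dialect). Only `expression.tsv` and `sample_type.tsv` are
#'   required; other layers are loaded when present.
#' @param cancer_code Cohort label.
#' @param gene_panel Optional character vector; when given, all matrices are
#'   restricted to these genes (exact, case-sensitive matching).
#' @return An `omics_cohort`.
#' @export
read_cohort <- function(dir, cancer_code, gene_panel = NULL) {
  expr_path <- file.path(dir, "expression.tsv")
  if (!file.exists(expr_path))
    stop("expression file not found: ", expr_path, call. = FALSE)
  expr <- .read_matrix(expr_path)
  st <- utils::read.delim(file.path(dir, "sample_type.tsv"),
                          stringsAsFactors = FALSE)
  sample_type <- stats::setNames(st$type, st$sample)
  maybe_matrix <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) .read_matrix(p) else NULL
  }
  cnv <- maybe_matrix("cnv.tsv")
  meth <- maybe_matrix("methylation.tsv")
  mut_path <- file.path(dir, "mutations.maf")
  mutations <- if (file.exists(mut_path)) read_maf(mut_path) else NULL
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path))
    utils::read.delim(clin_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(gene_panel)) {
    keep <- intersect(gene_panel, rownames(expr))
    expr <- expr[keep, , drop = FALSE]
    if (!is.null(cnv)) cnv <- cnv[intersect(gene_panel, rownames(cnv)), , drop = FALSE]
    if (!is.null(meth)) meth <- meth[intersect(gene_panel, rownames(meth)), , drop = FALSE]
  }
  new_omics_cohort(cancer_code, expr, sample_type, cnv = cnv,
                   methylation = meth, mutations = mutations,
                   clinical = clinical)
}

#' Write a pipeline result bundle
#'
#' Writes one tab-separated table per result class plus a run manifest
#' recording the seed and a hash of the configuration, so that two runs with
#' the same configuration and seed produce byte-identical output.
#'
#' @param results Named list of data frames (e.g. `dysregulation`,
#'   `drivers`, `mutation_summary`, `survival_calls`, `risk_models`,
#'   `associations`). NULL entries are skipped.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest.
#' @param config_hash Character hash of the run configuration.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, seed = NA_integer_,
                          config_hash = NA_character_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    tab <- results[[nm]]
    if (is.null(tab)) next
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(tab)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
      format(x, digits = 15, trim = TRUE, scientific = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    written <- c(written, p)
  }
  manifest <- file.path(out_dir, "run_manifest.txt")
  writeLines(c(sprintf("seed\t%s", seed),
               sprintf("config_hash\t%s", config_hash),
               sprintf("tables\t%s", paste(basename(written), collapse = ","))),
             manifest)
  invisible(c(written, manifest))
}

#' Hash a run configuration
#'
#' Deterministic md5 of the deparsed configuration object, used in the run
#' manifest.
#' @param config Any R object.
#' @return Character md5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  sets
}
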