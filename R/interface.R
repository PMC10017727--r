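#' Diagnosis stage from a HAM-D24 score
#'
#' Stages subjects by the 24-item Hamilton Depression Rating Scale: a score
#' of 8 or less is a healthy control (`HC`), 20-34 moderate depression
#' (`MD`), 35 or more severe depression (`SD`). Scores of 9-19 fall in the
#' gap between the control and patient definitions and return `NA`
#' (unclassified) with a warning; such subjects are excluded downstream.
#'
#' @param score integer vector of HAM-D24 total scores (nonnegative).
#' @return character vector of `"HC"`, `"MD"`, `"SD"` or `NA`.
#' @examples
#' stage_from_hamd(c(3, 27, 38, 15))
#' @export
stage_from_hamd <- function(score) {
  score <- as.numeric(score)
  if (any(score < 0, na.rm = TRUE))
    stop("HAM-D24 scores must be nonnegative", call. = FALSE)
  out <- rep(NA_character_, length(score))
  out[score <= 8] <- "HC"
  out[score >= 20 & score <= 34] <- "MD"
  out[score >= 35] <- "SD"
  gap <- !is.na(score) & score > 8 & score < 20
  if (any(gap))
    warning(sprintf("%d score(s) in the unclassified 9-19 gap set to NA",
                    sum(gap)), call. = FALSE)
  out
}

#' Additive coding of one SNP's genotype calls
#'
#' Splits allele-pair calls (e.g. `"A/C"`, `"AC"`), determines major and
#' minor alleles from the sample allele frequencies, and codes each subject
#' by the rule: homozygous major = 0, heterozygous = 1, homozygous
#' minor = 2. An exact 50/50 frequency tie makes the lexicographically
#' smaller allele "major" (deterministic, reported via message). Missing
#' calls (`NA`, `""`, `"./."`, `"00"`) code to `NA` and are listwise-dropped
#' downstream.
#'
#' @param calls character vector of genotype calls for one SNP.
#' @return list with `codes` (integer 0/1/2 or NA), `major`, `minor`,
#'   `n_missing`, and `monomorphic` flag (warned when TRUE).
#' @examples
#' code_genotype_additive(c("A/A", "A/C", "C/C", "A/A"))
#' @export
code_genotype_additive <- function(calls) {
  calls <- as.character(calls)
  miss <- is.na(calls) | calls %in% c("", "./.", "00", "0/0", "NN")
  if (all(miss)) stop("all genotype calls are missing", call. = FALSE)
  split_call <- function(x) {
    if (grepl("/", x, fixed = TRUE)) strsplit(x, "/", fixed = TRUE)[[1]]
    else strsplit(x, "")[[1]]
  }
  pairs <- lapply(calls[!miss], split_call)
  if (any(lengths(pairs) != 2L))
    stop("each genotype call must contain exactly two alleles", call. = FALSE)
  alleles <- unlist(pairs)
  freq <- sort(table(alleles), decreasing = TRUE)
  if (length(freq) > 2L)
    stop(sprintf("SNP is multi-allelic: alleles %s",
                 paste(names(freq), collapse = ", ")), call. = FALSE)
  if (length(freq) == 1L) {
    major <- names(freq)[1]
    minor <- NA_character_
    warning("monomorphic SNP: all subjects code to 0", call. = FALSE)
  } else if (freq[1] == freq[2]) {
    major <- min(names(freq))
    minor <- setdiff(names(freq), major)
    message(sprintf("allele-frequency tie: '%s' taken as major (lexicographic rule)",
                    major))
  } else {
    major <- names(freq)[1]
    minor <- names(freq)[2]
  }
  codes <- rep(NA_integer_, length(calls))
  codes[!miss] <- vapply(pairs, function(p) sum(p != major), integer(1))
  list(codes = codes, major = major, minor = minor,
       n_missing = sum(miss), monomorphic = length(freq) == 1L)
}

#' Read a feature table
#'
#' Tab-separated table: first column `subject_id`, remaining columns one per
#' ROI, numeric body. The inverse of [write_feature_table()]; the pair
#' round-trips values at full double precision.
#'
#' @param path file path.
#' @return numeric matrix with subject-id rownames and ROI colnames.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad_cell <- is.na(num) & !is.na(body) & body != "NA"
  if (any(bad_cell)) {
    bad <- which(bad_cell, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                 bad[1], colnames(body)[bad[2]], path), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write a feature table
#'
#' @param x numeric matrix with subject-id rownames and ROI colnames.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  x <- as.matrix(x)
  ids <- rownames(x) %||% sprintf("sub%04d", seq_len(nrow(x)))
  body <- format(x, digits = 17, trim = TRUE, scientific = TRUE)
  out <- cbind(subject_id = ids, body)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align modality feature tables (and optional cohort vectors) by subject
#'
#' Intersects subject ids across all tables, reports dropped subjects, and
#' checks that modalities agree on ROI (column) names.
#'
#' @param tables named list of feature matrices (rownames = subject ids).
#' @param require_same_columns check that all tables share identical column
#'   names (TRUE for the node/edge modality pair).
#' @return named list of matrices restricted to the common subjects, in a
#'   common order; attribute `dropped` lists excluded subject ids.
#' @export
align_modalities <- function(tables, require_same_columns = TRUE) {
  stopifnot(length(tables) >= 1L)
  if (require_same_columns) {
    ref <- colnames(tables[[1]])
    for (i in seq_along(tables)[-1]) {
      if (!identical(colnames(tables[[i]]), ref)) {
        off <- union(setdiff(colnames(tables[[i]]), ref),
                     setdiff(ref, colnames(tables[[i]])))
        stop(sprintf("ROI-name mismatch between modalities: %s",
                     paste(off, collapse = ", ")), call. = FALSE)
      }
    }
  }
  ids <- Reduce(intersect, lapply(tables, rownames))
  if (length(ids) == 0L) stop("no common subjects", call. = FALSE)
  dropped <- setdiff(unique(unlist(lapply(tables, rownames))), ids)
  if (length(dropped))
    message(sprintf("dropped %d subject(s) absent from some table: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  out <- lapply(tables, function(t) t[ids, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Import a PLINK additive-dosage (.raw) file
#'
#' Reads the text export of `plink --recode A`: six leading columns
#' (FID IID PAT MAT SEX PHENOTYPE) then one 0/1/2 dosage column per SNP.
#'
#' @param path file path.
#' @return numeric matrix (subjects x SNPs) with IID rownames; `NA` marks
#'   missing dosages.
#' @export
read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(tab)[seq_len(6)]))
    stop("not a PLINK .raw file: missing the six fixed leading columns",
         call. = FALSE)
  g <- as.matrix(tab[, -(1:6), drop = FALSE])
  storage.mode(g) <- "numeric"
  rownames(g) <- tab$IID
  g
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds, md5 checksums of the input files and
#' the package version — enough to re-run a pipeline step bit-for-bit. No
#' timestamps are written, so identical runs produce identical manifests.
#'
#' @param path output JSON path.
#' @param config named list of parameters for the step.
#' @param inputs character vector of input file paths to checksum.
#' @param seed the seed the step ran under.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character(),
                           seed = NULL) {
  sums <- if (length(inputs)) {
    s <- tools::md5sum(inputs)
    names(s) <- basename(inputs)  # path-independent, so reruns match
    as.list(s)
  } else list()
  obj <- list(
    package = "msdmm",
    version = as.character(utils::packageVersion("msdmm")),
    seed = seed,
    config = config,
    input_md5 = sums
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
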