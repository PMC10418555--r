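#' Canonical trait order of the phenotype challenge
#'
#' The seven clinical traits scored by the assessment, in the fixed column
#' order used by every submission and answer-key table: intellectual
#' disability (ID), autism spectrum disorder (ASD), epilepsy, microcephaly,
#' macrocephaly, hypotonia, ataxia.
#'
#' @return Character vector of length 7.
#' @export
panel_traits <- function() {
  c("ID", "ASD", "Epilepsy", "Microcephaly", "Macrocephaly",
    "Hypotonia", "Ataxia")
}

#' Define a challenge cohort
#'
#' Bundles the patient identifiers, the trait order and the captured gene
#' regions of the sequencing panel.  All downstream readers validate against
#' this definition.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param trait_names Character vector of unique trait labels; defaults to the
#'   seven-trait challenge order of [panel_traits()].
#' @param gene_regions Data frame with columns `chrom`, `start`, `end`,
#'   `gene`: half-open 0-based captured intervals (BED convention).
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(patient_ids,
                              trait_names = panel_traits(),
                              gene_regions = default_gene_regions()) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids))
    stopf("duplicated patient ids: %s",
          paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  if (anyDuplicated(trait_names))
    stopf("duplicated trait names")
  gene_regions <- validate_regions(gene_regions)
  structure(list(patient_ids = patient_ids,
                 trait_names = as.character(trait_names),
                 gene_regions = gene_regions),
            class = "cohort_definition")
}

validate_regions <- function(gene_regions) {
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(gene_regions)))
    stopf("gene_regions must have columns %s", paste(need, collapse = ", "))
  gene_regions$chrom <- normalize_chrom(gene_regions$chrom)
  bad <- which(gene_regions$start >= gene_regions$end)
  if (length(bad))
    stopf("gene region start >= end at row(s) %s", paste(bad, collapse = ", "))
  gene_regions
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat(sprintf("<cohort_definition> %d patients, %d traits, %d panel regions\n",
              length(x$patient_ids), length(x$trait_names),
              nrow(x$gene_regions)))
  invisible(x)
}

normalize_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
}

MISSING_MARK <- "*"
VARIANT_CLASSES <- c("DC", "LP", "CF")

## ---- variant keys ----------------------------------------------------------

#' Build a table of variant keys
#'
#' A variant key is the VCF-coordinate identity of a variant: chromosome
#' (without the "chr" prefix), 1-based position, reference and alternate
#' allele.  Validation enforces `ref != alt`, `pos >= 1` and bases in
#' `{A,C,G,T,N}`.
#'
#' @param chrom,pos,ref,alt Vectors of equal length (recycled per base R).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
variant_keys <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  bad_base <- grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt) |
    !nzchar(ref) | !nzchar(alt)
  if (any(bad_base))
    stopf("invalid allele string(s): %s",
          paste(unique(paste0(ref[bad_base], ">", alt[bad_base])), collapse = ", "))
  if (any(pos < 1L, na.rm = TRUE) || anyNA(pos))
    stopf("variant pos must be an integer >= 1")
  same <- ref == alt
  if (any(same))
    stopf("ref equals alt for variant(s) at %s",
          paste(paste0(chrom[same], ":", pos[same]), collapse = ", "))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Parse "chrom-pos-ref-alt" variant tokens
#'
#' Accepts `-` or `:` separators and an optional `chr` prefix, e.g.
#' `"chr1-12345-A-G"` or `"X:153296777:C:T"`.
#'
#' @param token Character vector of tokens.
#' @return Data frame of variant keys (see [variant_keys()]).
#' @export
parse_variant_token <- function(token) {
  token <- as.character(token)
  parts <- strsplit(token, "[-:]")
  bad <- lengths(parts) != 4L
  if (any(bad))
    stopf("malformed variant token(s): %s",
          paste(unique(token[bad]), collapse = ", "))
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  if (any(grepl("[^0-9]", m[, 2L])))
    stopf("malformed variant token(s): %s",
          paste(unique(token[grepl("[^0-9]", m[, 2L])]), collapse = ", "))
  variant_keys(m[, 1L], as.integer(m[, 2L]), m[, 3L], m[, 4L])
}

#' Format variant keys back into tokens
#' @param keys Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param sep Separator, `"-"` by default.
#' @return Character vector of tokens.
#' @export
format_variant_token <- function(keys, sep = "-") {
  paste(keys$chrom, keys$pos, keys$ref, keys$alt, sep = sep)
}

variant_id <- function(df) {
  paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

## ---- phenotype submission tables -------------------------------------------

#' Construct a phenotype probability submission
#'
#' @param probs Numeric matrix patients x traits with values in `[0,1]`;
#'   `NA` marks a cell the predictor left missing (`"*"` on disk).
#' @param submission_id,group_id Identifiers, e.g. `"8.6"` and `"8"`.
#' @return An object of class `phenotype_submission`.
#' @export
phenotype_submission <- function(probs, submission_id = "1.1",
                                 group_id = submission_group(submission_id)) {
  probs <- as.matrix(probs)
  bad <- which(!is.na(probs) & (probs < 0 | probs > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("probability outside [0,1] for patient %s, trait %s: %s",
          rownames(probs)[bad[1, 1]] %||% bad[1, 1],
          colnames(probs)[bad[1, 2]] %||% bad[1, 2],
          format(probs[bad[1, , drop = FALSE]]))
  structure(list(submission_id = as.character(submission_id),
                 group_id = as.character(group_id),
                 probs = probs),
            class = "phenotype_submission")
}

#' Group identifier of a submission id
#'
#' Submission ids follow the `"<group>.<model>"` convention (`"8.6"` is model 6
#' of group 8); the group id is the part before the dot.
#' @param submission_id Character vector.
#' @return Character vector of group ids.
#' @export
submission_group <- function(submission_id) {
  sub("\\..*$", "", as.character(submission_id))
}

#' @export
print.phenotype_submission <- function(x, ...) {
  cat(sprintf("<phenotype_submission %s (group %s)> %d patients x %d traits, %d missing cells\n",
              x$submission_id, x$group_id, nrow(x$probs), ncol(x$probs),
              sum(is.na(x$probs))))
  invisible(x)
}

read_trait_table <- function(path, cohort, what) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c("patient_id", cohort$trait_names)
  if (!identical(names(tab), expected))
    stopf("%s '%s': header must be: %s", what, path,
          paste(expected, collapse = "\t"))
  dup <- tab$patient_id[duplicated(tab$patient_id)]
  if (length(dup))
    stopf("%s '%s': duplicated patient id(s): %s", what, path,
          paste(unique(dup), collapse = ", "))
  unknown <- setdiff(tab$patient_id, cohort$patient_ids)
  if (length(unknown))
    stopf("%s '%s': unknown patient id(s): %s (first at row %d)", what, path,
          paste(unknown, collapse = ", "),
          which(tab$patient_id == unknown[1])[1])
  missing <- setdiff(cohort$patient_ids, tab$patient_id)
  if (length(missing))
    stopf("%s '%s': cohort patient(s) absent: %s", what, path,
          paste(missing, collapse = ", "))
  rownames(tab) <- tab$patient_id
  tab[cohort$patient_ids, cohort$trait_names, drop = FALSE]
}

#' Read a phenotype probability submission (TSV)
#'
#' Dialect: tab-separated, header `patient_id` followed by the seven trait
#' columns in canonical order, one row per cohort patient.  `"*"` marks a
#' missing prediction and is preserved as `NA` until imputation (see
#' [impute_missing()]); numeric cells must lie in `[0,1]`.
#'
#' @param path Path to the TSV file.
#' @param cohort A [cohort_definition()]; rows are reordered to its patient
#'   order and validated against it.
#' @param submission_id,group_id Identifiers attached to the result.
#' @return A `phenotype_submission`.
#' @export
read_phenotype_submission <- function(path, cohort, submission_id = "1.1",
                                      group_id = submission_group(submission_id)) {
  cells <- read_trait_table(path, cohort, "submission")
  probs <- matrix(NA_real_, nrow(cells), ncol(cells),
                  dimnames = dimnames(cells))
  for (j in seq_len(ncol(cells))) {
    v <- cells[[j]]
    miss <- v == MISSING_MARK
    num <- suppressWarnings(as.numeric(v))
    bad <- !miss & is.na(num)
    if (any(bad))
      stopf("submission '%s': non-numeric value '%s' for patient %s, trait %s",
            path, v[bad][1], rownames(cells)[bad][1], colnames(cells)[j])
    out <- which(!miss & (num < 0 | num > 1))
    if (length(out))
      stopf("submission '%s': probability out of [0,1] for patient %s, trait %s: %s",
            path, rownames(cells)[out[1]], colnames(cells)[j], v[out[1]])
    probs[, j] <- ifelse(miss, NA_real_, num)
  }
  phenotype_submission(probs, submission_id, group_id)
}

#' Write a phenotype submission (TSV)
#' @param sub A `phenotype_submission`.
#' @param path Output path; missing cells are written as `"*"`, probabilities
#'   with 6 decimals.
#' @export
write_phenotype_submission <- function(sub, path) {
  m <- sub$probs
  chr <- matrix(MISSING_MARK, nrow(m), ncol(m), dimnames = dimnames(m))
  chr[!is.na(m)] <- formatC(m[!is.na(m)], digits = 6, format = "f")
  write_trait_table(chr, path)
}

write_trait_table <- function(chr, path) {
  tab <- data.frame(patient_id = rownames(chr), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---- phenotype answer key --------------------------------------------------

#' Construct a phenotype answer key
#'
#' Tri-state truth labels per patient and trait: `"positive"`, `"negative"`
#' or `"unknown"`.  Unknown labels are legal — for several traits the
#' laboratory's positive and negative counts do not cover the whole cohort —
#' and are excluded from confusion counts downstream.
#'
#' @param labels Character matrix patients x traits over the three states.
#' @return An object of class `phenotype_answer_key` (a character matrix).
#' @export
phenotype_answer_key <- function(labels) {
  labels <- as.matrix(labels)
  ok <- labels %in% c("positive", "negative", "unknown")
  if (!all(ok))
    stopf("answer-key labels must be positive/negative/unknown; saw: %s",
          paste(unique(labels[!ok]), collapse = ", "))
  structure(labels, class = "phenotype_answer_key")
}

#' @export
print.phenotype_answer_key <- function(x, ...) {
  cat(sprintf("<phenotype_answer_key> %d patients x %d traits (%d positive labels)\n",
              nrow(x), ncol(x), sum(x == "positive")))
  invisible(x)
}

#' Read a phenotype answer key (TSV)
#'
#' Same tabular dialect as submissions, with cells `positive`, `negative` or
#' `unknown` (case-insensitive).
#' @inheritParams read_phenotype_submission
#' @return A `phenotype_answer_key`.
#' @export
read_phenotype_answer_key <- function(path, cohort) {
  cells <- read_trait_table(path, cohort, "answer key")
  m <- tolower(as.matrix(cells))
  dimnames(m) <- dimnames(cells)
  phenotype_answer_key(m)
}

#' Write a phenotype answer key (TSV)
#' @param key A `phenotype_answer_key`.
#' @param path Output path.
#' @export
write_phenotype_answer_key <- function(key, path) {
  write_trait_table(unclass(key), path)
}

## ---- variant tables --------------------------------------------------------

#' Construct a classified variant answer key
#'
#' The laboratory's ground truth for the variant track: one row per
#' (patient, variant) with a class label — `DC` (disease causing), `LP`
#' (likely pathogenic / putative) or `CF` (contributing factor).
#'
#' @param patient_id Character vector.
#' @param keys Data frame of variant keys ([variant_keys()]), same length.
#' @param class Character vector over `DC`, `LP`, `CF`.
#' @return Data frame of class `variant_answer_key` with columns
#'   `patient_id`, `chrom`, `pos`, `ref`, `alt`, `class`.
#' @export
variant_answer_key <- function(patient_id, keys, class) {
  class <- toupper(as.character(class))
  if (!all(class %in% VARIANT_CLASSES))
    stopf("variant class must be one of %s",
          paste(VARIANT_CLASSES, collapse = ", "))
  df <- cbind(data.frame(patient_id = as.character(patient_id),
                         stringsAsFactors = FALSE),
              keys, data.frame(class = class, stringsAsFactors = FALSE))
  if (anyDuplicated(variant_id(df)))
    stopf("duplicated (patient, variant) entries in answer key")
  structure(df, class = c("variant_answer_key", "data.frame"))
}

#' Construct a variant prediction set
#'
#' A submission's predicted (patient, variant) pairs; a patient may have zero
#' entries.  Duplicate (patient, variant) pairs are removed with a message so
#' repeated listing cannot inflate the prediction count.
#'
#' @param patient_id Character vector (may be empty).
#' @param keys Data frame of variant keys, same length.
#' @param score Optional numeric score per entry.
#' @param submission_id,group_id Identifiers.
#' @return Data frame of class `variant_prediction_set`.
#' @export
variant_prediction_set <- function(patient_id, keys, score = NULL,
                                   submission_id = "1.1",
                                   group_id = submission_group(submission_id)) {
  df <- cbind(data.frame(patient_id = as.character(patient_id),
                         stringsAsFactors = FALSE), keys)
  df$score <- if (is.null(score)) rep(NA_real_, nrow(df))
              else as.numeric(score)
  dup <- duplicated(variant_id(df))
  if (any(dup)) {
    message(sprintf("variant_prediction_set %s: dropping %d duplicated (patient, variant) entr%s",
                    submission_id, sum(dup), if (sum(dup) == 1) "y" else "ies"))
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("variant_prediction_set", "data.frame"),
            submission_id = as.character(submission_id),
            group_id = as.character(group_id))
}

#' Read a variant answer key (TSV: patient_id, token, class)
#' @param path Path to the file.
#' @return A `variant_answer_key`.
#' @export
read_variant_answer_key <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("patient_id", "variant", "class") %in% names(tab)))
    stopf("answer key '%s' needs columns patient_id, variant, class", path)
  variant_answer_key(tab$patient_id, parse_variant_token(tab$variant),
                     tab$class)
}

#' Write a variant answer key (TSV)
#' @param key A `variant_answer_key`.
#' @param path Output path.
#' @export
write_variant_answer_key <- function(key, path) {
  utils::write.table(data.frame(patient_id = key$patient_id,
                                variant = format_variant_token(key),
                                class = key$class),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a variant prediction set (TSV: patient_id, token[, score])
#' @param path Path to the file.
#' @param submission_id,group_id Identifiers attached to the result.
#' @return A `variant_prediction_set`.
#' @export
read_variant_predictions <- function(path, submission_id = "1.1",
                                     group_id = submission_group(submission_id)) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("patient_id", "variant") %in% names(tab)))
    stopf("prediction file '%s' needs columns patient_id, variant", path)
  score <- if ("score" %in% names(tab)) as.numeric(tab$score) else NULL
  variant_prediction_set(tab$patient_id, parse_variant_token(tab$variant),
                         score, submission_id, group_id)
}

#' Write a variant prediction set (TSV)
#' @param vp A `variant_prediction_set`.
#' @param path Output path.
#' @export
write_variant_predictions <- function(vp, path) {
  tab <- data.frame(patient_id = vp$patient_id,
                    variant = format_variant_token(vp))
  if (!all(is.na(vp$score))) tab$score <- vp$score
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---- submission validation -------------------------------------------------

violation <- function(kind, patient_id = NA_character_, trait = NA_character_,
                      detail = "") {
  if (!length(kind))
    return(data.frame(kind = character(0), patient_id = character(0),
                      trait = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  data.frame(kind = kind, patient_id = patient_id, trait = trait,
             detail = detail, stringsAsFactors = FALSE)
}

#' Validate a submission pair against a cohort definition
#'
#' Pure check mirroring the validation script distributed with the challenge:
#' violations are returned as data, never raised.  An empty result means the
#' phenotype table and the variant predictions satisfy every structural
#' invariant (patients known and complete, probabilities in range or missing,
#' variant chromosomes on the panel).
#'
#' @param sub A `phenotype_submission` (or `NULL` to skip).
#' @param vp A `variant_prediction_set` (or `NULL` to skip).
#' @param cohort A `cohort_definition`.
#' @return Data frame with columns `kind`, `patient_id`, `trait`, `detail`;
#'   zero rows when valid.
#' @export
validate_submission <- function(sub = NULL, vp = NULL, cohort) {
  out <- list()
  if (!is.null(sub)) {
    ids <- rownames(sub$probs)
    for (p in setdiff(ids, cohort$patient_ids))
      out[[length(out) + 1L]] <- violation("UNKNOWN_PATIENT", p)
    for (p in setdiff(cohort$patient_ids, ids))
      out[[length(out) + 1L]] <- violation("MISSING_PATIENT", p)
    for (p in unique(ids[duplicated(ids)]))
      out[[length(out) + 1L]] <- violation("DUPLICATE_PATIENT", p)
    bad <- which(!is.na(sub$probs) & (sub$probs < 0 | sub$probs > 1),
                 arr.ind = TRUE)
    for (i in seq_len(nrow(bad)))
      out[[length(out) + 1L]] <-
        violation("PROB_OUT_OF_RANGE", ids[bad[i, 1]],
                  colnames(sub$probs)[bad[i, 2]],
                  format(sub$probs[bad[i, , drop = FALSE]]))
    if (!identical(colnames(sub$probs), cohort$trait_names))
      out[[length(out) + 1L]] <- violation("TRAIT_ORDER", detail =
        paste(colnames(sub$probs), collapse = ","))
  }
  if (!is.null(vp) && nrow(vp)) {
    for (p in unique(setdiff(vp$patient_id, cohort$patient_ids)))
      out[[length(out) + 1L]] <- violation("UNKNOWN_PATIENT", p)
    panel_chroms <- unique(cohort$gene_regions$chrom)
    off <- unique(setdiff(vp$chrom, panel_chroms))
    for (ch in off)
      out[[length(out) + 1L]] <-
        violation("OFF_PANEL_CHROM", detail = ch)
  }
  if (!length(out)) return(violation(character(0)))
  do.call(rbind, out)
}

## ---- VCF -------------------------------------------------------------------

#' Read a single-sample VCF 4.2 file
#'
#' Parses a plain-text VCF through `vcfR` and returns one row per alternate
#' allele (multi-allelic records are split; the genotype string is carried
#' unchanged onto each split entry).  FORMAT fields `GT`, `DP`, `GQ` and the
#' record `QUAL` are extracted; a FORMAT field absent from the file is kept
#' as `NA` and reported once per file.
#'
#' @param path Path to an uncompressed VCF.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `gt`, `dp`, `gq`, in file order.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), gt = character(0),
                      dp = integer(0), gq = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0L) return(empty)
  fix <- v@fix
  fmt <- function(el, fn) {
    if (ncol(v@gt) < 2L || !any(grepl(el, v@gt[, "FORMAT"]))) {
      message(sprintf("read_vcf '%s': FORMAT field %s absent; kept as NA",
                      path, el))
      return(rep(NA, nrow(fix)))
    }
    fn(vcfR::extract.gt(v, element = el)[, 1L])
  }
  gt <- fmt("GT", as.character)
  dp <- fmt("DP", function(x) as.integer(x))
  gq <- fmt("GQ", function(x) as.integer(x))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  data.frame(chrom = normalize_chrom(fix[idx, "CHROM"]),
             pos = as.integer(fix[idx, "POS"]),
             ref = fix[idx, "REF"],
             alt = unlist(alts),
             qual = suppressWarnings(as.numeric(fix[idx, "QUAL"])),
             gt = gt[idx], dp = dp[idx], gq = gq[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a single-sample VCF 4.2 file
#'
#' Counterpart of [read_vcf()]: emits records with QUAL and FORMAT `GT:DP:GQ`.
#' Entries sharing `chrom`/`pos`/`ref` are written as separate records (no
#' multi-allelic re-joining), which round-trips through [read_vcf()] exactly.
#'
#' @param records Data frame as returned by [read_vcf()].
#' @param path Output path.
#' @param sample_id Sample column name.
#' @export
write_vcf <- function(records, path, sample_id = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelbench",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(records)) {
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  formatC(records$qual, format = "fg", digits = 6), "PASS", ".",
                  "GT:DP:GQ",
                  paste(records$gt, records$dp, records$gq, sep = ":"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- BED -------------------------------------------------------------------

#' Read a BED4 file of captured gene regions
#'
#' Half-open 0-based intervals, kept verbatim (no merging of overlaps).  At
#' least four columns are required — the fourth is the gene symbol; lines
#' violating `start < end` raise an error naming the line.
#'
#' @param path Path to the BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 4L)
  if (length(short))
    stopf("BED '%s': line %d has %d column(s); 4 required (gene symbol)",
          path, which(keep)[short[1]], lengths(parts)[short[1]])
  m <- t(vapply(parts, function(p) p[1:4], character(4)))
  start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stopf("BED '%s': start >= end (or non-numeric) at line %d", path,
          which(keep)[bad[1]])
  data.frame(chrom = normalize_chrom(m[, 1L]), start = start, end = end,
             gene = m[, 4L], stringsAsFactors = FALSE)
}

#' Write gene regions as BED4
#' @param gene_regions Data frame with `chrom`, `start`, `end`, `gene`.
#' @param path Output path.
#' @export
write_bed <- function(gene_regions, path) {
  writeLines(paste(gene_regions$chrom, gene_regions$start, gene_regions$end,
                   gene_regions$gene, sep = "\t"), path)
  invisible(path)
}
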