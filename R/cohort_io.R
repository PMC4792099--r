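## Reading/writing of the four input file families and the result tables.
## Patient CNV and control files are 1-based inclusive on disk; everything is
## converted to 0-based half-open internally (see intervals.R).

CNV_CLASSES <- c("gain", "loss")
INHERITANCE_LEVELS <- c("de_novo", "inherited_unaffected",
                        "inherited_affected", "unknown")

#' Patient cohort container
#'
#' A \code{pel_cohort} bundles the two patient-level inputs: a CNV table and
#' the per-patient phenotype annotations. Only patients with at least one CNV
#' and at least one phenotype term are retained (patients without ontology
#' annotations are dropped, mirroring the usual genotype-first study design);
#' the dropped ids are kept for audit.
#'
#' @param cnvs data.frame with columns \code{patient_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{class}
#'   (\code{"gain"}/\code{"loss"}), \code{inheritance}.
#' @param phenotypes named list: patient id -> character vector of term ids.
#' @param dropped character vector of patient ids excluded for lacking
#'   phenotype annotations.
#' @return an object of class \code{"pel_cohort"}.
#' @export
pel_cohort <- function(cnvs, phenotypes, dropped = character()) {
  stopifnot(is.data.frame(cnvs), is.list(phenotypes))
  req <- c("patient_id", "chrom", "start", "end", "class", "inheritance")
  miss <- setdiff(req, names(cnvs))
  if (length(miss)) stop("cnvs missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(cnvs$class), CNV_CLASSES)
  if (length(bad))
    stop("unknown CNV class '", bad[1], "'; allowed: ",
         paste(CNV_CLASSES, collapse = ", "))
  bad <- setdiff(unique(cnvs$inheritance), INHERITANCE_LEVELS)
  if (length(bad))
    stop("unknown inheritance '", bad[1], "'; allowed: ",
         paste(INHERITANCE_LEVELS, collapse = ", "))
  if (any(cnvs$end <= cnvs$start)) stop("CNV with end <= start")
  ids <- unique(cnvs$patient_id)
  if (!all(ids %in% names(phenotypes)))
    stop("patients without phenotype entry: ",
         paste(utils::head(setdiff(ids, names(phenotypes)), 3), collapse = ", "))
  if (any(lengths(phenotypes[ids]) == 0L))
    stop("patient with empty phenotype set")
  rownames(cnvs) <- NULL
  structure(list(cnvs = cnvs, phenotypes = phenotypes[ids],
                 dropped = dropped),
            class = "pel_cohort")
}

#' @export
print.pel_cohort <- function(x, ...) {
  cat(sprintf("Patient cohort: %d patients, %d CNVs (%d gain / %d loss), %d dropped without phenotypes\n",
              length(x$phenotypes), nrow(x$cnvs),
              sum(x$cnvs$class == "gain"), sum(x$cnvs$class == "loss"),
              length(x$dropped)))
  cat(sprintf("  terms per patient: median %s; distinct terms: %d\n",
              stats::median(lengths(x$phenotypes)),
              length(unique(unlist(x$phenotypes)))))
  invisible(x)
}

#' @export
#' @rdname pel_cohort
#' @param x a \code{pel_cohort}
cohort_patients <- function(x) names(x$phenotypes)

#' Read a patient CNV table plus phenotype annotations
#'
#' The CNV file is tab-separated with header columns \code{patient_id},
#' \code{chrom}, \code{start}, \code{end} (1-based inclusive), \code{class}
#' (gain/loss) and \code{inheritance}; the annotation file is tab-separated
#' with columns \code{patient_id} and \code{terms} (pipe-separated term ids).
#' Patients present in the CNV table but absent from (or empty in) the
#' annotation table are dropped and reported in the returned object.
#'
#' @param cnv_path path to the CNV table.
#' @param annotation_path path to the annotation table.
#' @param cnv_filter optional predicate taking the raw CNV data.frame and
#'   returning a logical row mask (e.g. a platform filter); applied before
#'   validation.
#' @return a [pel_cohort].
#' @export
read_patient_cnvs <- function(cnv_path, annotation_path, cnv_filter = NULL) {
  for (p in c(cnv_path, annotation_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.delim(cnv_path, colClasses = "character")
  req <- c("patient_id", "chrom", "start", "end", "class", "inheritance")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("CNV file missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(cnv_filter)) raw <- raw[cnv_filter(raw), , drop = FALSE]
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start) | is.na(end) | raw$patient_id == "")
  if (length(bad))
    stop("malformed CNV row at line ", bad[1] + 1L, " of ", cnv_path)
  bad <- which(end < start)
  if (length(bad))
    stop("CNV with end < start at line ", bad[1] + 1L, " of ", cnv_path)
  cnvs <- data.frame(patient_id = raw$patient_id, chrom = raw$chrom,
                     start = to_internal_start(start), end = end,
                     class = raw$class, inheritance = raw$inheritance,
                     stringsAsFactors = FALSE)

  ann <- utils::read.delim(annotation_path, colClasses = "character")
  if (!all(c("patient_id", "terms") %in% names(ann)))
    stop("annotation file missing columns: patient_id, terms")
  terms <- strsplit(ann$terms, "|", fixed = TRUE)
  terms <- lapply(terms, function(t) unique(t[nzchar(t)]))
  names(terms) <- ann$patient_id
  terms <- terms[lengths(terms) > 0L]

  ids <- unique(cnvs$patient_id)
  keep <- ids %in% names(terms)
  dropped <- ids[!keep]
  cnvs <- cnvs[cnvs$patient_id %in% ids[keep], , drop = FALSE]
  if (!nrow(cnvs)) stop("no patients with both CNVs and phenotype annotations")
  pel_cohort(cnvs, terms, dropped = dropped)
}

#' Write a patient cohort back to the file formats it was read from
#'
#' Coordinates are converted back to 1-based inclusive. Reading the written
#' pair with [read_patient_cnvs] reproduces the cohort field-by-field.
#'
#' @param cohort a [pel_cohort].
#' @param cnv_path,annotation_path output paths.
#' @export
write_patient_cnvs <- function(cohort, cnv_path, annotation_path) {
  out <- cohort$cnvs
  out$start <- format(to_external_start(out$start), scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, cnv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(patient_id = names(cohort$phenotypes),
                    terms = vapply(cohort$phenotypes, paste,
                                   character(1), collapse = "|"),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Default mapping from structural-variant subtypes to gain/loss
#'
#' Control catalogues in the DGV dialect annotate richer subtypes than the
#' gain/loss dichotomy used here; subtypes not in the map are skipped.
#' @export
default_subtype_map <- function() {
  c(gain = "gain", duplication = "gain", insertion = "gain",
    loss = "loss", deletion = "loss")
}

#' Read a control structural-variant table (DGV dialect)
#'
#' Tab-separated with a header; the chromosome, start, end and variant
#' subtype columns are located by name (\code{chr}/\code{chrom},
#' \code{start}, \code{end}, \code{variantsubtype}/\code{subtype}), with an
#' optional \code{samples} column of comma-separated sample ids. Coordinates
#' are 1-based inclusive on disk. Subtypes are mapped to gain/loss via
#' \code{subtype_map}; unmapped subtypes are skipped and counted. Rows whose
#' samples field lists several ids are expanded to one record per sample.
#'
#' @param path file path.
#' @param subtype_map named character vector, subtype -> gain/loss.
#' @param n_ctrl override for the control population size; defaults to the
#'   number of distinct sample ids when a samples column is present, else
#'   the record count.
#' @return an object of class \code{"control_set"}: list with
#'   \code{variants} (data.frame sample_id/chrom/start/end/class, 0-based
#'   half-open), \code{n_ctrl} and \code{n_skipped}.
#' @export
read_control_variants <- function(path, subtype_map = default_subtype_map(),
                                  n_ctrl = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character")
  pick <- function(cands) {
    hit <- intersect(cands, tolower(names(raw)))
    if (!length(hit)) stop("control file missing required column: ",
                           cands[1])
    names(raw)[match(hit[1], tolower(names(raw)))]
  }
  c_chr <- pick(c("chr", "chrom", "chromosome"))
  c_start <- pick(c("start"))
  c_end <- pick(c("end", "stop"))
  c_sub <- pick(c("variantsubtype", "subtype", "varianttype"))
  has_samples <- any(tolower(names(raw)) == "samples")

  subtype <- tolower(raw[[c_sub]])
  cls <- unname(subtype_map[subtype])
  keep <- !is.na(cls)
  n_skipped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]; cls <- cls[keep]
  start <- suppressWarnings(as.numeric(raw[[c_start]]))
  end <- suppressWarnings(as.numeric(raw[[c_end]]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  sample_id <- if (has_samples) {
    s <- raw[[names(raw)[match("samples", tolower(names(raw)))]]]
    ifelse(nzchar(s), s, paste0("record_", seq_len(nrow(raw))))
  } else paste0("record_", seq_len(nrow(raw)))
  v <- data.frame(sample_id = sample_id,
                  chrom = sub("^chr", "", raw[[c_chr]]),
                  start = to_internal_start(start), end = end,
                  class = cls, stringsAsFactors = FALSE)
  # expand multi-sample rows so carrier counting sees individual samples
  multi <- grepl(",", v$sample_id, fixed = TRUE)
  if (any(multi)) {
    reps <- strsplit(v$sample_id, ",", fixed = TRUE)
    v <- v[rep(seq_len(nrow(v)), lengths(reps)), , drop = FALSE]
    v$sample_id <- trimws(unlist(reps))
  }
  control_set(v, n_ctrl = n_ctrl, n_skipped = n_skipped)
}

#' @rdname read_control_variants
#' @param variants data.frame of control variants (internal coordinates).
#' @param n_skipped count of records dropped by the subtype map.
#' @export
control_set <- function(variants, n_ctrl = NULL, n_skipped = 0L) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "class") %in%
                  names(variants)))
  if (any(variants$end <= variants$start)) stop("control variant with end <= start")
  bad <- setdiff(unique(variants$class), CNV_CLASSES)
  if (length(bad)) stop("unknown control variant class: ", bad[1])
  if (is.null(n_ctrl)) n_ctrl <- length(unique(variants$sample_id))
  rownames(variants) <- NULL
  structure(list(variants = variants, n_ctrl = as.integer(n_ctrl),
                 n_skipped = as.integer(n_skipped)),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("Control set: %d variants, %d distinct samples (N_ctrl = %d), %d records skipped by subtype map\n",
              nrow(x$variants), length(unique(x$variants$sample_id)),
              x$n_ctrl, x$n_skipped))
  invisible(x)
}

#' Write control variants in the DGV-dialect format
#' @param controls a \code{control_set}.
#' @param path output path.
#' @export
write_control_variants <- function(controls, path) {
  v <- controls$variants
  out <- data.frame(chr = v$chrom,
                    start = format(to_external_start(v$start),
                                   scientific = FALSE, trim = TRUE),
                    end = format(v$end, scientific = FALSE, trim = TRUE),
                    variantsubtype = ifelse(v$class == "gain",
                                            "duplication", "deletion"),
                    samples = v$sample_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write the PEL association table and companion BED file
#'
#' The table is tab-separated, 1-based inclusive coordinates, sorted by
#' ascending BH-adjusted Fisher p; the BED file carries the same loci in
#' 0-based half-open convention for genome-browser use.
#'
#' @param associations data.frame of PEL associations (see [associate_pels]).
#' @param path output TSV path.
#' @param bed_path output BED path; default replaces the extension with .bed.
#' @export
write_pel_table <- function(associations, path,
                            bed_path = paste0(tools::file_path_sans_ext(path), ".bed")) {
  cols <- c("pel_id", "class", "chrom", "start", "end", "length_kb",
            "phenotype_id", "phenotype_name", "cases_with_phenotype",
            "clique_size", "control_carriers", "enrichment_p",
            "fisher_p_raw", "fisher_p_bh", "penetrance_pct")
  if (nrow(associations)) {
    a <- associations[order(associations$p_fisher_bh, associations$chrom,
                            associations$start), , drop = FALSE]
    out <- data.frame(pel_id = a$pel_id, class = a$class, chrom = a$chrom,
                      start = to_external_start(a$start), end = a$end,
                      length_kb = round((a$end - a$start) / 1000, 3),
                      phenotype_id = a$term_id,
                      phenotype_name = a$term_name,
                      cases_with_phenotype = a$k_case,
                      clique_size = a$n_clique,
                      control_carriers = a$m_ctrl,
                      enrichment_p = a$p_enrich,
                      fisher_p_raw = a$p_fisher_raw,
                      fisher_p_bh = a$p_fisher_bh,
                      penetrance_pct = a$penetrance_pct,
                      stringsAsFactors = FALSE)
    names(out) <- cols
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    bed <- unique(data.frame(chrom = a$chrom,
                             start = format(a$start, scientific = FALSE, trim = TRUE),
                             end = format(a$end, scientific = FALSE, trim = TRUE),
                             name = a$pel_id, stringsAsFactors = FALSE))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(paste(cols, collapse = "\t"), path)
    file.create(bed_path)
  }
  invisible(NULL)
}

#' Read a known-syndrome interval catalogue
#'
#' BED-like tab-separated file with header columns \code{chrom},
#' \code{start}, \code{end} (1-based inclusive), \code{name},
#' \code{mutation_type} (gain/loss) and optional \code{source}.
#'
#' @param path file path.
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
read_syndromes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character")
  req <- c("chrom", "start", "end", "name", "mutation_type")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("syndrome file missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(raw$mutation_type), CNV_CLASSES)
  if (length(bad)) stop("unknown syndrome mutation_type: ", bad[1])
  data.frame(name = raw$name, chrom = raw$chrom,
             start = to_internal_start(as.numeric(raw$start)),
             end = as.numeric(raw$end), mutation_type = raw$mutation_type,
             source = if ("source" %in% names(raw)) raw$source else NA_character_,
             stringsAsFactors = FALSE)
}
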