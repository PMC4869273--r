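#' Allele catalogues
#'
#' An `allele_catalogue` is the reference collection of MHC class I allele
#' cDNA sequences that reads are aligned against.  It holds, per allele, an
#' identifier, a gene label parsed from IPD-style nomenclature
#' (`BoLA-<gene>*<group><protein>`), the classical/non-classical class, the
#' provenance (database record, novel variant of a parent allele, or de novo
#' assembly) and the parent allele for novel variants.
#'
#' @param allele_id character vector of unique allele identifiers.
#' @param sequence character vector of cDNA sequences over `{A,C,G,T,N}`.
#' @param class_kind `"classical"` or `"nonclassical"`, recycled.
#' @param gene_label gene labels; parsed from `allele_id` when `NULL`.
#' @param provenance `"database"`, `"novel_variant"` or `"novel_de_novo"`,
#'   recycled.
#' @param parent_id parent allele id per allele (`NA` unless provenance is
#'   `"novel_variant"`).
#' @param version_tag free-text catalogue version tag.
#' @param max_n_frac maximum tolerated fraction of `N` per sequence.
#' @return an object of class `allele_catalogue`: a list with a data frame
#'   `alleles`, a named character vector `sequences`, a `version_tag` and the
#'   `novel_counter` used to number newly added alleles.
#' @export
allele_catalogue <- function(allele_id = character(), sequence = character(),
                             class_kind = "classical", gene_label = NULL,
                             provenance = "database", parent_id = NA_character_,
                             version_tag = "v1", max_n_frac = 0) {
  allele_id <- as.character(allele_id)
  sequence <- normalise_seq(as.character(sequence))
  n <- length(allele_id)
  stopifnot(length(sequence) == n)
  if (anyDuplicated(allele_id)) {
    stop("duplicate allele identifier(s): ",
         paste(unique(allele_id[duplicated(allele_id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for allele(s): ",
         paste(allele_id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence of: ",
         paste(allele_id[bad], collapse = ", "))
  }
  nfrac <- vapply(sequence, function(s) {
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1), USE.NAMES = FALSE)
  if (n > 0 && any(nfrac > max_n_frac)) {
    stop("N content above ", max_n_frac, " for allele(s): ",
         paste(allele_id[nfrac > max_n_frac], collapse = ", "))
  }
  class_kind <- rep_len(as.character(class_kind), n)
  stopifnot(all(class_kind %in% c("classical", "nonclassical")))
  if (is.null(gene_label)) gene_label <- parse_gene_label(allele_id)
  gene_label <- rep_len(as.character(gene_label), n)
  provenance <- rep_len(as.character(provenance), n)
  stopifnot(all(provenance %in% c("database", "novel_variant",
                                  "novel_de_novo")))
  parent_id <- rep_len(as.character(parent_id), n)
  if (any(provenance == "novel_variant" & is.na(parent_id)) ||
      any(provenance != "novel_variant" & !is.na(parent_id))) {
    stop("parent_id must be set exactly for novel_variant alleles")
  }
  sequences <- stats::setNames(sequence, allele_id)
  structure(
    list(alleles = data.frame(allele_id = allele_id, gene_label = gene_label,
                              class_kind = class_kind, provenance = provenance,
                              parent_id = parent_id,
                              stringsAsFactors = FALSE),
         sequences = sequences, version_tag = version_tag,
         novel_counter = 1L),
    class = "allele_catalogue")
}

#' @export
print.allele_catalogue <- function(x, ...) {
  cat("allele_catalogue [", x$version_tag, "]: ", nrow(x$alleles),
      " alleles (", sum(x$alleles$class_kind == "classical"), " classical, ",
      sum(x$alleles$class_kind == "nonclassical"), " non-classical; ",
      sum(x$alleles$provenance != "database"), " novel)\n", sep = "")
  invisible(x)
}

#' @export
length.allele_catalogue <- function(x) nrow(x$alleles)

#' Parse the gene label from IPD-style allele names
#'
#' Names of the form `<prefix>-<gene>*<group><protein>` (for example
#' `BoLA-2*01601` or `BoLA-NC1*00101`, with or without a novel-allele suffix)
#' yield the `<gene>` part; anything non-conforming yields `"UNASSIGNED"`.
#'
#' @param allele_id character vector of allele names.
#' @return character vector of gene labels.
#' @export
parse_gene_label <- function(allele_id) {
  out <- rep("UNASSIGNED", length(allele_id))
  has_star <- grepl("*", allele_id, fixed = TRUE)
  left <- sub("\\*.*$", "", allele_id[has_star])
  gene <- sub("^.*-", "", left)
  ok <- grepl("-", left, fixed = TRUE) & nzchar(gene)
  out[has_star][ok] <- gene[ok]
  out
}

#' Load an allele catalogue from FASTA
#'
#' Reads one allele per FASTA record.  The allele id is the first
#' whitespace-delimited token of the header; gene labels are parsed from the
#' id (see [parse_gene_label()]); sequences are uppercased and `U` is
#' converted to `T`.
#'
#' @param fasta_source path to a FASTA file.
#' @param class_kind class assigned to every record: `"classical"` or
#'   `"nonclassical"`.
#' @param version_tag catalogue version tag; defaults to the file name.
#' @return an [allele_catalogue()].
#' @export
load_catalogue <- function(fasta_source, class_kind = "classical",
                           version_tag = basename(fasta_source)) {
  ss <- Biostrings::readBStringSet(fasta_source)
  ids <- sub("\\s.*$", "", names(ss))
  allele_catalogue(allele_id = ids, sequence = as.character(ss),
                   class_kind = class_kind, version_tag = version_tag)
}

#' Write an allele catalogue to FASTA
#'
#' Headers carry the allele id plus `gene=` and `class=` attributes; sequences
#' are wrapped at 60 columns.  [load_catalogue()] of the written file
#' round-trips ids and sequences byte-identically.
#'
#' @param cat an [allele_catalogue()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "allele_catalogue"))
  ss <- Biostrings::BStringSet(cat$sequences)
  names(ss) <- paste0(cat$alleles$allele_id, " gene=", cat$alleles$gene_label,
                      " class=", cat$alleles$class_kind)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Merge two allele catalogues
#'
#' Union preserving order (first catalogue then second).  A duplicated allele
#' id across the inputs is an error; identical sequences filed under
#' different ids are retained with a warning, since closely related MHC
#' class I alleles assigned to different genes may share a sequence.
#'
#' @param a,b [allele_catalogue()] objects.
#' @return the merged [allele_catalogue()].
#' @export
merge_catalogues <- function(a, b) {
  stopifnot(inherits(a, "allele_catalogue"), inherits(b, "allele_catalogue"))
  clash <- intersect(a$alleles$allele_id, b$alleles$allele_id)
  if (length(clash)) {
    stop("allele id(s) present in both catalogues: ",
         paste(clash, collapse = ", "))
  }
  dup <- intersect(a$sequences, b$sequences)
  if (length(dup)) {
    ids <- c(names(a$sequences)[a$sequences %in% dup],
             names(b$sequences)[b$sequences %in% dup])
    warning("identical sequence under different ids retained: ",
            paste(ids, collapse = ", "))
  }
  out <- a
  out$alleles <- rbind(a$alleles, b$alleles)
  rownames(out$alleles) <- NULL
  out$sequences <- c(a$sequences, b$sequences)
  out$version_tag <- paste(a$version_tag, b$version_tag, sep = "+")
  out$novel_counter <- max(a$novel_counter, b$novel_counter)
  out
}

#' Add a newly discovered allele to a catalogue
#'
#' Novel variants of a known parent get ids of the form
#' `<parent_id>_<lab_tag><n>`; de novo alleles without an assignable parent
#' get `<un_prefix>_<lab_tag><n>`.  `n` is the catalogue's novel counter,
#' which increases with every addition.
#'
#' @param cat an [allele_catalogue()].
#' @param sequence the novel cDNA sequence (must differ from every sequence
#'   already in the catalogue).
#' @param parent_id id of the parent allele, or `NULL` for a de novo allele.
#' @param lab_tag laboratory tag used in the generated id.
#' @param class_kind class of a de novo allele (ignored when a parent is
#'   given: the parent's class and gene label are inherited).
#' @param un_prefix id prefix for de novo alleles.
#' @return list with elements `catalogue` (the extended catalogue) and
#'   `allele_id` (the id assigned to the new allele).
#' @export
add_novel_allele <- function(cat, sequence, parent_id = NULL, lab_tag = "FBN",
                             class_kind = NULL, un_prefix = "BoLA_UN") {
  stopifnot(inherits(cat, "allele_catalogue"), length(sequence) == 1L)
  sequence <- normalise_seq(sequence)
  hit <- which(cat$sequences == sequence)
  if (length(hit)) {
    stop("sequence already present in catalogue as ",
         names(cat$sequences)[hit[1L]])
  }
  n <- cat$novel_counter
  if (!is.null(parent_id)) {
    if (!parent_id %in% cat$alleles$allele_id) {
      stop("unknown parent allele: ", parent_id)
    }
    row <- cat$alleles[cat$alleles$allele_id == parent_id, ]
    id <- paste0(parent_id, "_", lab_tag, n)
    new <- data.frame(allele_id = id, gene_label = row$gene_label,
                      class_kind = row$class_kind,
                      provenance = "novel_variant", parent_id = parent_id,
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(class_kind)) {
      stop("class_kind is required for a de novo allele without parent")
    }
    stopifnot(class_kind %in% c("classical", "nonclassical"))
    id <- paste0(un_prefix, "_", lab_tag, n)
    new <- data.frame(allele_id = id, gene_label = "UNASSIGNED",
                      class_kind = class_kind, provenance = "novel_de_novo",
                      parent_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (id %in% cat$alleles$allele_id) {
    stop("generated id collides with existing allele: ", id)
  }
  cat$alleles <- rbind(cat$alleles, new)
  rownames(cat$alleles) <- NULL
  cat$sequences <- c(cat$sequences, stats::setNames(sequence, id))
  cat$novel_counter <- n + 1L
  list(catalogue = cat, allele_id = id)
}

#' Translate an allele and report MHC class I protein features
#'
#' Translates the cDNA under the chosen frame policy and reports whether a
#' full open reading frame is present, whether a stop codon occurs strictly
#' before the final codon (an early stop, typical of non-classical null-like
#' alleles) and which of the transmembrane motifs `VLIK`, `VPI` or `IPI`
#' (longest first) occurs in the translated protein.
#'
#' @param allele either an allele id present in `cat`, or a nucleotide
#'   sequence when `cat` is `NULL`.
#' @param frame_policy `"first_atg"` (translate from the first `ATG`) or
#'   `"fixed_frame"` (translate from `frame`).
#' @param cat optional [allele_catalogue()] to resolve `allele` in.
#' @param frame 1-based frame offset used by `"fixed_frame"` (1, 2 or 3).
#' @return a list of class `protein_report` with fields `allele_id`,
#'   `aa_sequence` (translation up to, not including, the first stop),
#'   `has_orf`, `early_stop` and `tm_motif` (`"VLIK"`, `"VPI"`, `"IPI"` or
#'   `"none"`).
#' @export
translate_allele <- function(allele, frame_policy = c("first_atg",
                                                      "fixed_frame"),
                             cat = NULL, frame = 1L) {
  frame_policy <- match.arg(frame_policy)
  if (!is.null(cat)) {
    stopifnot(inherits(cat, "allele_catalogue"),
              allele %in% cat$alleles$allele_id)
    id <- allele
    seq <- unname(cat$sequences[[allele]])
  } else {
    id <- NA_character_
    seq <- normalise_seq(allele)
  }
  stopifnot(nchar(seq) >= 3L)
  start <- if (frame_policy == "first_atg") {
    as.integer(regexpr("ATG", seq, fixed = TRUE))
  } else {
    as.integer(frame)
  }
  empty <- structure(list(allele_id = id, aa_sequence = "", has_orf = FALSE,
                          early_stop = FALSE, tm_motif = "none"),
                     class = "protein_report")
  if (start < 1L || start > nchar(seq) - 2L) return(empty)
  cds <- substr(seq, start, nchar(seq))
  ncod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  stops <- which(aa == "*")
  first_stop <- if (length(stops)) stops[1L] else NA_integer_
  early <- !is.na(first_stop) && first_stop < ncod
  aa_seq <- if (is.na(first_stop)) {
    paste(aa, collapse = "")
  } else {
    paste(aa[seq_len(first_stop - 1L)], collapse = "")
  }
  motif <- "none"
  for (m in c("VLIK", "VPI", "IPI")) {
    if (grepl(m, aa_seq, fixed = TRUE)) {
      motif <- m
      break
    }
  }
  structure(list(allele_id = id, aa_sequence = aa_seq,
                 has_orf = frame_policy == "fixed_frame" || !early,
                 early_stop = early, tm_motif = motif),
            class = "protein_report")
}

#' @export
print.protein_report <- function(x, ...) {
  cat("protein_report", if (!is.na(x$allele_id)) x$allele_id else "",
      ": ", nchar(x$aa_sequence), " aa; has_orf=", x$has_orf,
      " early_stop=", x$early_stop, " tm_motif=", x$tm_motif, "\n", sep = "")
  invisible(x)
}

#' Protein feature reports for a whole catalogue
#'
#' @param cat an [allele_catalogue()].
#' @param ... passed to [translate_allele()].
#' @return data frame with one row per allele: `allele_id`, `has_orf`,
#'   `early_stop`, `tm_motif`.
#' @export
protein_reports <- function(cat, ...) {
  reps <- lapply(cat$alleles$allele_id, translate_allele, cat = cat, ...)
  data.frame(allele_id = cat$alleles$allele_id,
             has_orf = vapply(reps, `[[`, logical(1), "has_orf"),
             early_stop = vapply(reps, `[[`, logical(1), "early_stop"),
             tm_motif = vapply(reps, `[[`, character(1), "tm_motif"),
             stringsAsFactors = FALSE)
}

#' Write protein feature reports as TSV
#'
#' @param reports data frame from [protein_reports()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_reports <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Amino-acid positions discriminating two allele groups
#'
#' Given two groups of aligned, equal-length amino-acid sequences, returns
#' every aligned column where the residue sets of the two groups are
#' disjoint.  Columns in which any sequence carries a gap character `-` are
#' skipped unless `include_gap_columns` is `TRUE`.
#'
#' @param aligned_aa_group_a,aligned_aa_group_b character vectors of aligned
#'   amino-acid sequences; all sequences in both groups must share one
#'   length.
#' @param include_gap_columns include columns containing gaps?
#' @return data frame with 0-based `position`, and comma-separated residue
#'   sets `residues_a` and `residues_b`, one row per discriminating column.
#' @export
group_discriminating_positions <- function(aligned_aa_group_a,
                                           aligned_aa_group_b,
                                           include_gap_columns = FALSE) {
  a <- as.character(aligned_aa_group_a)
  b <- as.character(aligned_aa_group_b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  len <- unique(nchar(c(a, b)))
  if (length(len) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  ma <- do.call(rbind, strsplit(a, ""))
  mb <- do.call(rbind, strsplit(b, ""))
  hits <- lapply(seq_len(len), function(j) {
    ra <- unique(ma[, j])
    rb <- unique(mb[, j])
    if (!include_gap_columns && ("-" %in% ra || "-" %in% rb)) return(NULL)
    ra_res <- setdiff(ra, "-")
    rb_res <- setdiff(rb, "-")
    if (!length(ra_res) || !length(rb_res) ||
        length(intersect(ra_res, rb_res)) > 0L) {
      return(NULL)
    }
    data.frame(position = j - 1L,
               residues_a = paste(sort(setdiff(ra, "-")), collapse = ","),
               residues_b = paste(sort(setdiff(rb, "-")), collapse = ","),
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(position = integer(0), residues_a = character(0),
                      residues_b = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
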