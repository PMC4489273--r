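#' @importFrom stats phyper p.adjust ks.test sd setNames
#' @importFrom utils combn head write.table
NULL

# Canonical interaction-type tokens and the node classes they imply.
INTERACTION_TYPES <- c("TF2gene", "TF2miRNA", "miRNA2gene", "miRNA2miRNA")

TYPE_CLASSES <- list(
  TF2gene     = c(regulator = "TF",    target = "gene"),
  TF2miRNA    = c(regulator = "TF",    target = "miRNA"),
  miRNA2gene  = c(regulator = "miRNA", target = "gene"),
  miRNA2miRNA = c(regulator = "miRNA", target = "miRNA")
)

#' Default miRNA identifier prefixes
#'
#' Identifiers are treated as opaque strings throughout the package; the only
#' convention is that miRNA IDs are recognizable by prefix (case-insensitive),
#' so that flat ID lists can be split into gene/TF and miRNA classes.
#'
#' @return Character vector of prefixes.
#' @export
mirna_id_prefixes <- function() c("hsa-mir", "hsa-let")

#' Test whether identifiers look like miRNA IDs
#'
#' @param ids character vector of identifiers.
#' @param prefixes prefix list, matched case-insensitively at the start of
#'   the identifier.
#' @return logical vector.
#' @export
is_mirna_id <- function(ids, prefixes = mirna_id_prefixes()) {
  if (length(ids) == 0L) return(logical(0))
  pat <- paste0("^(", paste(sub("([.|()\\^{}+$*?\\[\\]\\\\-])", "\\\\\\1",
                                prefixes), collapse = "|"), ")")
  grepl(pat, ids, ignore.case = TRUE)
}

#' Construct an interaction database from a records data frame
#'
#' An `interaction_db` holds one row per typed, evidence-tagged
#' regulator -> target edge.  Duplicate (regulator, target, type) triples are
#' collapsed; when duplicates disagree on evidence, `validated` wins.
#'
#' @param records data frame with columns `regulator`, `target`,
#'   `interaction_type`, `evidence`, `source`.
#' @return An object of class `interaction_db`: list with elements
#'   `records` (the deduplicated data frame, with derived `regulator_class`
#'   and `target_class` columns) and `universes` (per interaction type, the
#'   regulator and target ID sets).
#' @export
interaction_db <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("regulator", "target", "interaction_type", "evidence", "source")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  bad_type <- !records$interaction_type %in% INTERACTION_TYPES
  if (any(bad_type))
    stop("unknown interaction_type token(s): ",
         paste(unique(records$interaction_type[bad_type]), collapse = ", "))
  bad_ev <- !records$evidence %in% c("validated", "predicted")
  if (any(bad_ev))
    stop("unknown evidence token(s): ",
         paste(unique(records$evidence[bad_ev]), collapse = ", "))

  records <- records[, need, drop = FALSE]
  for (cl in need) records[[cl]] <- as.character(records[[cl]])

  # validated dominates: order validated first, keep first of each triple
  ord <- order(records$evidence != "validated")
  records <- records[ord, , drop = FALSE]
  key <- paste(records$regulator, records$target, records$interaction_type,
               sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL

  cls <- do.call(rbind, TYPE_CLASSES[records$interaction_type])
  records$regulator_class <- if (nrow(records)) cls[, "regulator"] else character(0)
  records$target_class    <- if (nrow(records)) cls[, "target"] else character(0)

  universes <- lapply(setNames(INTERACTION_TYPES, INTERACTION_TYPES), function(tp) {
    sub <- records[records$interaction_type == tp, , drop = FALSE]
    list(regulators = unique(sub$regulator), targets = unique(sub$target))
  })
  structure(list(records = records, universes = universes),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat("Interaction database:", nrow(x$records), "records\n")
  tab <- table(factor(x$records$interaction_type, levels = INTERACTION_TYPES))
  for (tp in INTERACTION_TYPES)
    cat(sprintf("  %-12s %d\n", tp, tab[[tp]]))
  invisible(x)
}

#' Read a typed interaction table
#'
#' Reads a tab-separated file with columns regulator, target,
#' interaction_type, evidence, source ("#" lines are comments; a header row
#' is auto-detected).  Exact duplicate interactions are removed; duplicates
#' that disagree only on evidence collapse to `validated`.
#'
#' @param path file path.
#' @param evidence_filter keep only `"validated"`, only `"predicted"`, or
#'   `"both"` (default).
#' @param quiet suppress the per-type record count message.
#' @return An [interaction_db()] object.
#' @export
read_interaction_table <- function(path,
                                   evidence_filter = c("both", "validated", "predicted"),
                                   quiet = FALSE) {
  evidence_filter <- match.arg(evidence_filter)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  # a header row is allowed only as the first row
  has_header <- nf[1] >= 3L && !fields[[1]][3] %in% INTERACTION_TYPES
  if (has_header) bad <- setdiff(bad, 1L)
  if (length(bad))
    stop("malformed row (expected >= 5 tab-separated fields) at line ",
         lineno[bad[1]], " of ", path)
  if (has_header) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (!length(fields)) stop("no data rows in ", path)

  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  records <- data.frame(regulator = trimws(m[, 1]), target = trimws(m[, 2]),
                        interaction_type = trimws(m[, 3]),
                        evidence = trimws(m[, 4]), source = trimws(m[, 5]),
                        stringsAsFactors = FALSE)
  bad_type <- which(!records$interaction_type %in% INTERACTION_TYPES)
  if (length(bad_type))
    stop("unknown interaction_type '", records$interaction_type[bad_type[1]],
         "' at line ", lineno[bad_type[1]], " of ", path)
  db <- interaction_db(records)
  if (evidence_filter != "both") {
    recs <- db$records[db$records$evidence == evidence_filter,
                       c("regulator", "target", "interaction_type",
                         "evidence", "source"), drop = FALSE]
    db <- interaction_db(recs)
    if (nrow(db$records) == 0L)
      warning("no records left after evidence filter '", evidence_filter, "'")
  }
  if (!quiet) {
    tab <- table(factor(db$records$interaction_type, levels = INTERACTION_TYPES))
    message("loaded ", nrow(db$records), " interactions (",
            paste(sprintf("%s=%d", INTERACTION_TYPES, tab), collapse = ", "), ")")
  }
  db
}

#' Write an interaction database to TSV
#'
#' @param db an [interaction_db()].
#' @param path output file.
#' @export
write_interaction_table <- function(db, path) {
  stopifnot(inherits(db, "interaction_db"))
  write.table(db$records[, c("regulator", "target", "interaction_type",
                             "evidence", "source")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text identifier list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' identifiers are trimmed and deduplicated.
#'
#' @param path file path.
#' @return character vector (a set).
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[!grepl("^(#|$)", lines)])
  if (!length(ids)) stop("no usable identifiers in ", path)
  ids
}

#' Construct an annotation table
#'
#' Maps term IDs to entity-ID sets, the generic container used for
#' over-representation analysis and functional-similarity scoring.
#'
#' @param terms named list of character vectors (term_id -> entity IDs);
#'   every set must be non-empty.
#' @param term_names optional named character vector of human-readable names.
#' @return object of class `annotation_table`.
#' @export
annotation_table <- function(terms, term_names = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, function(x) unique(as.character(x)))
  if (any(lengths(terms) == 0L))
    stop("annotation term(s) with empty entity set: ",
         paste(names(terms)[lengths(terms) == 0L], collapse = ", "))
  if (is.null(term_names))
    term_names <- setNames(names(terms), names(terms))
  structure(list(terms = terms, term_names = term_names[names(terms)]),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", length(x$terms), "terms,",
      length(unique(unlist(x$terms))), "annotated entities\n")
  invisible(x)
}

#' Read a GMT annotation file
#'
#' Format: `term_id <tab> term_name <tab> id1 <tab> id2 ...`.
#'
#' @param path file path.
#' @return an [annotation_table()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no terms in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("malformed GMT row (need term_id, term_name, >=1 id) in ", path)
  ids <- vapply(fields, `[`, "", 1L)
  nms <- vapply(fields, `[`, "", 2L)
  annotation_table(setNames(lapply(fields, function(f) f[-(1:2)]), ids),
                   setNames(nms, ids))
}

#' Write an annotation table as GMT
#'
#' @param annotations an [annotation_table()].
#' @param path output file.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  lines <- vapply(names(annotations$terms), function(id) {
    paste(c(id, annotations$term_names[[id]], annotations$terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Invert an annotation table to an entity -> term map
#'
#' @param annotations an [annotation_table()].
#' @return named list: entity ID -> character vector of term IDs.
#' @export
entity_terms <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  ent <- unlist(annotations$terms, use.names = FALSE)
  trm <- rep(names(annotations$terms), lengths(annotations$terms))
  split(trm, ent)
}

#' Construct disease associations
#'
#' @param disease disease name.
#' @param genes associated gene/TF IDs.
#' @param mirnas associated miRNA IDs.
#' @return object of class `disease_assoc`.
#' @export
disease_associations <- function(disease, genes = character(),
                                 mirnas = character()) {
  structure(list(disease = as.character(disease)[1],
                 genes = unique(as.character(genes)),
                 mirnas = unique(as.character(mirnas))),
            class = "disease_assoc")
}

#' Read a disease-association table
#'
#' TSV with columns disease, entity ID and (optionally) entity class
#' (`gene` / `miRNA`); without the class column the miRNA prefix convention
#' decides.
#'
#' @param path file path.
#' @param disease restrict to one disease name (default: first seen).
#' @param prefixes miRNA prefix convention, see [mirna_id_prefixes()].
#' @return a [disease_associations()] object.
#' @export
read_disease_associations <- function(path, disease = NULL,
                                      prefixes = mirna_id_prefixes()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (fields[[1]][1] %in% c("disease", "Disease")) fields <- fields[-1]
  if (any(lengths(fields) < 2L)) stop("malformed disease-association row in ", path)
  dis <- vapply(fields, `[`, "", 1L)
  id <- trimws(vapply(fields, `[`, "", 2L))
  cls <- vapply(fields, function(f) if (length(f) >= 3L) f[3] else NA_character_, "")
  if (is.null(disease)) disease <- dis[1]
  sel <- dis == disease
  if (!any(sel)) stop("disease '", disease, "' not found in ", path)
  id <- id[sel]; cls <- cls[sel]
  is_mir <- ifelse(is.na(cls), is_mirna_id(id, prefixes),
                   tolower(cls) %in% c("mirna", "mir"))
  disease_associations(disease, genes = id[!is_mir], mirnas = id[is_mir])
}
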