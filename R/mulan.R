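# Mulan-dialect multi-label data files: a Weka ARFF (dense or sparse body)
# carrying attribute AND label columns, plus an XML file that is the sole
# authority on which columns are labels. Sparse rows use 0-based
# "{index value, ...}" entries and omit zeros. No installed R reader handles
# the sparse body, so the codec lives here; foreign::read.arff cross-checks
# the dense writer in the test suite.

.strip_quotes <- function(x) {
  q <- (startsWith(x, "'") & endsWith(x, "'")) |
    (startsWith(x, "\"") & endsWith(x, "\""))
  x[q] <- substr(x[q], 2, nchar(x[q]) - 1)
  x
}

.quote_name <- function(x) {
  needs <- grepl("[ ,%{}']", x)
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs]), "'")
  x
}

# split "@attribute name type" into name/type, honouring quoted names
.parse_attr_decl <- function(line) {
  rest <- sub("^@attribute[ \t]+", "", line, ignore.case = TRUE)
  if (startsWith(rest, "'") || startsWith(rest, "\"")) {
    q <- substr(rest, 1, 1)
    end <- regexpr(paste0(q, "[ \t]"), substr(rest, 2, nchar(rest)))
    if (end < 0) stop("unterminated quoted attribute name: ", line)
    name <- substr(rest, 2, end)
    type <- trimws(substr(rest, end + 2, nchar(rest)))
  } else {
    sp <- regexpr("[ \t]", rest)
    if (sp < 0) stop("malformed @attribute line: ", line)
    name <- substr(rest, 1, sp - 1)
    type <- trimws(substr(rest, sp + 1, nchar(rest)))
  }
  list(name = name, type = type)
}

#' Read a Mulan multi-label dataset (ARFF + label XML)
#'
#' Parses a Weka ARFF file (dense or sparse body) together with the Mulan XML
#' file naming which columns are labels. Label columns are removed from the
#' attribute space and materialised as per-instance label sets (value 1 means
#' the instance carries the label). A leading string attribute named
#' `protein_id` (written by [write_mulan()]) supplies instance identifiers;
#' otherwise ids `instance_1 ... instance_n` are generated. Instances with
#' reserved `__EMPTY_*` ids are flagged as padding.
#'
#' @param arff_path Path to the ARFF file.
#' @param xml_path Path to the label XML file.
#' @return An `ml_dataset`.
#' @export
read_mulan <- function(arff_path, xml_path) {
  lines <- readLines(arff_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*%", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_attr <- grepl("^@attribute\\b", lines, ignore.case = TRUE)
  data_at <- which(grepl("^@data\\b", lines, ignore.case = TRUE))[1]
  if (is.na(data_at)) stop("ARFF file has no @data section")
  decls <- lapply(lines[seq_len(data_at - 1)][is_attr[seq_len(data_at - 1)]],
                  .parse_attr_decl)
  names_all <- .strip_quotes(vapply(decls, `[[`, "", "name"))
  types <- vapply(decls, `[[`, "", "type")
  kind_all <- ifelse(grepl("^\\{", types), "binary",
                     ifelse(grepl("^(numeric|real|integer)$", types,
                                  ignore.case = TRUE), "numeric",
                            ifelse(grepl("^string$", types, ignore.case = TRUE),
                                   "string", NA)))
  if (anyNA(kind_all)) {
    stop("unsupported ARFF attribute type: ",
         types[which(is.na(kind_all))[1]])
  }
  nominal <- which(kind_all == "binary")
  for (jj in nominal) {
    vals <- trimws(strsplit(gsub("[{}]", "", types[jj]), ",")[[1]])
    if (!setequal(vals, c("0", "1"))) {
      stop("nominal attribute '", names_all[jj], "' is not binary {0,1}")
    }
  }
  id_col <- which(kind_all == "string" & names_all == "protein_id")
  if (any(kind_all == "string" & !(seq_along(kind_all) %in% id_col))) {
    stop("string attributes other than 'protein_id' are not supported")
  }

  rows <- lines[seq(data_at + 1, length.out = max(0, length(lines) - data_at))]
  p <- length(names_all)
  n <- length(rows)
  vals <- matrix(0, nrow = n, ncol = p)
  chr_id <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    row <- rows[r]
    if (startsWith(row, "{")) {
      body <- trimws(sub("\\}\\s*$", "", sub("^\\{", "", row)))
      if (nzchar(body)) {
        for (entry in trimws(strsplit(body, ",")[[1]])) {
          sp <- regexpr("[ \t]", entry)
          if (sp < 0) stop("malformed sparse entry '", entry, "'")
          j <- as.integer(substr(entry, 1, sp - 1)) + 1L
          v <- .strip_quotes(trimws(substr(entry, sp + 1, nchar(entry))))
          if (j < 1 || j > p) stop("sparse index out of range in row ", r)
          if (length(id_col) && j == id_col) chr_id[r] <- v
          else vals[r, j] <- as.numeric(v)
        }
      }
    } else {
      fields <- .strip_quotes(trimws(strsplit(row, ",")[[1]]))
      if (length(fields) != p) {
        stop("dense row ", r, " has ", length(fields), " fields, expected ", p)
      }
      if (length(id_col)) {
        chr_id[r] <- fields[id_col]
        fields <- fields[-id_col]
        vals[r, -id_col] <- as.numeric(fields)
      } else {
        vals[r, ] <- as.numeric(fields)
      }
    }
  }
  ids <- if (length(id_col)) chr_id else sprintf("instance_%d", seq_len(n))
  if (anyNA(ids)) stop("missing protein_id value in data row")
  keep <- setdiff(seq_len(p), id_col)
  vals <- vals[, keep, drop = FALSE]
  colnames(vals) <- names_all[keep]
  kind <- kind_all[keep]

  label_names <- read_label_xml(xml_path)
  miss <- setdiff(label_names, colnames(vals))
  if (length(miss)) {
    stop("label(s) in XML not present among ARFF columns: ",
         paste(miss, collapse = ", "))
  }
  lab_idx <- match(label_names, colnames(vals))
  lab_vals <- vals[, lab_idx, drop = FALSE]
  if (!all(lab_vals %in% c(0, 1))) stop("label column with value outside {0,1}")
  labels <- lapply(seq_len(n), function(r) label_names[lab_vals[r, ] == 1])
  Xa <- vals[, -lab_idx, drop = FALSE]
  bin <- which(kind[-lab_idx] == "binary")
  if (length(bin) && !all(Xa[, bin] %in% c(0, 1))) {
    stop("binary attribute with value outside {0,1}")
  }
  ml_dataset(ids, Xa, labels, label_space = label_names,
             attr_kind = kind[-lab_idx],
             padding = grepl("^__EMPTY_", ids))
}

#' Read a Mulan label XML file
#'
#' @param xml_path Path to the XML file (`<labels><label name="..."/>...`).
#' @return Character vector of label names, in file order.
#' @export
read_label_xml <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='label']")
  out <- xml2::xml_attr(nodes, "name")
  if (anyNA(out)) stop("label element without a name attribute")
  out
}

#' Write a Mulan multi-label dataset (ARFF + label XML)
#'
#' Emits the ARFF with a leading `protein_id` string attribute, the dataset's
#' attribute columns, and the label columns appended last as binary `{0,1}`
#' attributes (Mulan convention), plus the XML naming the label columns.
#' Sparse rows list only nonzero entries as 0-based index-value pairs, so an
#' empty instance is the row `{0 id}`. `read_mulan()` inverts the output
#' exactly.
#'
#' @param dataset An `ml_dataset`.
#' @param arff_path Output ARFF path.
#' @param xml_path Output XML path; defaults to `arff_path` with `.xml`.
#' @param sparse Write the sparse body? (default `TRUE`).
#' @param relation ARFF relation name.
#' @return Invisibly, `c(arff_path, xml_path)`.
#' @export
write_mulan <- function(dataset, arff_path, xml_path = NULL, sparse = TRUE,
                        relation = "mechknn") {
  stopifnot(inherits(dataset, "ml_dataset"))
  if (is.null(xml_path)) xml_path <- sub("(\\.arff)?$", ".xml", arff_path)
  attrs <- colnames(dataset$X)
  labs <- dataset$label_space
  decl_type <- function(kind) if (kind == "binary") "{0,1}" else "numeric"
  header <- c(
    sprintf("@relation %s", relation),
    "",
    "@attribute protein_id string",
    sprintf("@attribute %s %s", .quote_name(attrs),
            vapply(dataset$attr_kind, decl_type, "")),
    sprintf("@attribute %s {0,1}", .quote_name(labs)),
    "",
    "@data")
  L <- matrix(0, nrow = length(dataset$ids), ncol = length(labs))
  for (r in seq_along(dataset$labels)) {
    L[r, match(dataset$labels[[r]], labs)] <- 1
  }
  full <- cbind(as.matrix(dataset$X), L)
  fmt_val <- function(v) {
    ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
           format(v, digits = 15, scientific = FALSE, trim = TRUE))
  }
  body <- character(nrow(full))
  for (r in seq_len(nrow(full))) {
    if (sparse) {
      nz <- which(full[r, ] != 0)
      ent <- c(sprintf("0 %s", dataset$ids[r]),
               if (length(nz)) sprintf("%d %s", nz, fmt_val(full[r, nz])))
      body[r] <- paste0("{", paste(ent, collapse = ", "), "}")
    } else {
      body[r] <- paste(c(dataset$ids[r], fmt_val(full[r, ])), collapse = ",")
    }
  }
  writeLines(c(header, body), arff_path)
  write_label_xml(labs, xml_path)
  invisible(c(arff_path, xml_path))
}

#' Write a Mulan label XML file
#' @param labels Character vector of label names.
#' @param xml_path Output path.
#' @return Invisibly, `xml_path`.
#' @export
write_label_xml <- function(labels, xml_path) {
  doc <- xml2::xml_new_root("labels",
                            xmlns = "http://mulan.sourceforge.net/labels")
  for (l in labels) xml2::xml_add_child(doc, "label", name = l)
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}
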