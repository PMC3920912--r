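#' Read a multilabel dataset
#'
#' Three on-disk dialects are supported (documented in the README):
#'
#' * `"mulan-arff"`: a dense ARFF file whose trailing nominal `{0,1}`
#'   attributes are the labels, with a companion XML file
#'   (`<labels><label name="..."/>...</labels>`) listing the label attribute
#'   names, as used by the Mulan library. `path` is the `.arff` file;
#'   `xml` defaults to the same path with extension `.xml`.
#' * `"pair-tsv+mtx"`: features as a MatrixMarket file (`path`, usually
#'   `.mtx`), labels as a TSV of `doc_id<TAB>label_id` pairs (0-based ids) in
#'   `<path-sans-ext>.pairs.tsv`, and a sidecar header
#'   `<path-sans-ext>.labels.tsv` (`label_id<TAB>name`, 0-based, in the
#'   persisted label order) so label order is reproducible across runs.
#' * `"dense-tsv"`: features as a dense TSV with a header row; labels and
#'   label names in the same two sidecar files as `pair-tsv+mtx`.
#'
#' @param path path to the main file (see above).
#' @param format one of `"mulan-arff"`, `"pair-tsv+mtx"`, `"dense-tsv"`.
#' @param xml for `"mulan-arff"`, path to the label-list XML.
#' @param role `"train"` (rows with zero labels rejected) or `"test"`.
#' @return a [multilabel_dataset].
#' @seealso [write_multilabel()]
#' @export
read_multilabel <- function(path,
                            format = c("mulan-arff", "pair-tsv+mtx", "dense-tsv"),
                            xml = NULL, role = "train") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    "mulan-arff" = read_mulan_arff(path, xml, role),
    "pair-tsv+mtx" = {
      X <- methods::as(Matrix::readMM(path), "CsparseMatrix")
      read_with_pair_sidecars(X, path, role)
    },
    "dense-tsv" = {
      df <- utils::read.delim(path, check.names = FALSE)
      X <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
      read_with_pair_sidecars(X, path, role)
    }
  )
}

#' Write a multilabel dataset
#'
#' Inverse of [read_multilabel()]; `read_multilabel(write_multilabel(ds, p, f), f)`
#' reproduces `ds` (exactly for MatrixMarket, to 15 significant digits for
#' ARFF).
#'
#' @param ds a [multilabel_dataset].
#' @param path output path for the main file.
#' @param format one of `"mulan-arff"`, `"pair-tsv+mtx"`, `"dense-tsv"`.
#' @return `path`, invisibly.
#' @export
write_multilabel <- function(ds,
                             path,
                             format = c("mulan-arff", "pair-tsv+mtx", "dense-tsv")) {
  stopifnot(inherits(ds, "multilabel_dataset"))
  format <- match.arg(format)
  switch(format,
    "mulan-arff" = write_mulan_arff(ds, path),
    "pair-tsv+mtx" = {
      Matrix::writeMM(ds$X, path)
      write_pair_sidecars(ds, path)
    },
    "dense-tsv" = {
      df <- as.data.frame(as.matrix(ds$X))
      names(df) <- ds$feature_names
      utils::write.table(df, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      write_pair_sidecars(ds, path)
    }
  )
  invisible(path)
}

sidecar_paths <- function(path) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", path)
  list(pairs = paste0(stem, ".pairs.tsv"), labels = paste0(stem, ".labels.tsv"))
}

read_with_pair_sidecars <- function(X, path, role) {
  sc <- sidecar_paths(path)
  for (f in unlist(sc)) {
    if (!file.exists(f)) stop("missing sidecar file: ", f, call. = FALSE)
  }
  lab <- utils::read.delim(sc$labels, colClasses = c("integer", "character"))
  if (!all(c("label_id", "name") %in% names(lab))) {
    stop("parse error in ", sc$labels, " line 1: expected columns label_id, name",
         call. = FALSE)
  }
  lab <- lab[order(lab$label_id), ]
  m <- nrow(lab)
  pairs <- utils::read.delim(sc$pairs)
  if (!all(c("doc_id", "label_id") %in% names(pairs))) {
    stop("parse error in ", sc$pairs, " line 1: expected columns doc_id, label_id",
         call. = FALSE)
  }
  n <- nrow(X)
  bad_doc <- which(pairs$doc_id < 0 | pairs$doc_id >= n)
  if (length(bad_doc)) {
    stop("doc id out of range in ", sc$pairs, " line ", bad_doc[1] + 1L,
         ": ", pairs$doc_id[bad_doc[1]], call. = FALSE)
  }
  bad_lab <- which(pairs$label_id < 0 | pairs$label_id >= m)
  if (length(bad_lab)) {
    stop("label id out of range in ", sc$pairs, " line ", bad_lab[1] + 1L,
         ": ", pairs$label_id[bad_lab[1]], call. = FALSE)
  }
  Y <- Matrix::sparseMatrix(i = pairs$doc_id + 1L, j = pairs$label_id + 1L,
                            x = 1, dims = c(n, m))
  Y@x[] <- 1  # collapse duplicate pairs
  multilabel_dataset(X, Y, label_names = lab$name, role = role)
}

write_pair_sidecars <- function(ds, path) {
  sc <- sidecar_paths(path)
  idx <- Matrix::which(ds$Y != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.table(
    data.frame(doc_id = idx[, 1] - 1L, label_id = idx[, 2] - 1L),
    sc$pairs, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(label_id = seq_along(ds$label_names) - 1L, name = ds$label_names),
    sc$labels, sep = "\t", row.names = FALSE, quote = FALSE)
}

mulan_xml_path <- function(path, xml) {
  xml %||% paste0(sub("\\.arff$", "", path, ignore.case = TRUE), ".xml")
}

read_mulan_arff <- function(path, xml, role) {
  xml <- mulan_xml_path(path, xml)
  if (!file.exists(xml)) stop("missing label XML: ", xml, call. = FALSE)
  doc <- xml2::read_xml(xml)
  label_names <- xml2::xml_attr(xml2::xml_find_all(doc, ".//label"), "name")
  if (!length(label_names)) {
    stop("validation error: no <label> entries in ", xml, call. = FALSE)
  }
  df <- tryCatch(foreign::read.arff(path), error = function(e) {
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  missing_lab <- setdiff(label_names, names(df))
  if (length(missing_lab)) {
    stop("label attribute(s) listed in XML but absent from ARFF: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  ycols <- df[label_names]
  Y <- vapply(ycols, function(col) as.numeric(as.character(col)),
              numeric(nrow(df)))
  if (nrow(df) == 1L) Y <- matrix(Y, nrow = 1L)
  feat <- setdiff(names(df), label_names)
  X <- as.matrix(df[feat])
  multilabel_dataset(X, Y, label_names = label_names, feature_names = feat,
                     role = role)
}

write_mulan_arff <- function(ds, path) {
  df <- as.data.frame(as.matrix(ds$X))
  names(df) <- ds$feature_names
  Yd <- as.matrix(ds$Y)
  for (j in seq_along(ds$label_names)) {
    df[[ds$label_names[j]]] <- factor(Yd[, j], levels = c(0, 1))
  }
  foreign::write.arff(df, path, relation = "multilabel")
  labs <- xml2::xml_new_root("labels")
  for (nm in ds$label_names) {
    xml2::xml_add_child(labs, "label", name = nm)
  }
  xml2::write_xml(labs, mulan_xml_path(path, NULL))
  invisible(path)
}
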