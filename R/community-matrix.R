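#' Construct and validate a community matrix
#'
#' A community matrix is a numeric samples x taxa matrix of non-negative
#' abundances (integer counts or fluorescence-derived relative abundances),
#' with unique sample ids as row names and unique taxon ids as column names.
#'
#' @param x numeric matrix, samples in rows, taxa in columns.
#' @param is_counts logical; `TRUE` when entries are integer counts. Defaults
#'   to auto-detection (all entries integral).
#' @param require_positive_rows logical; error if any sample has no positive
#'   entry (the default — downstream similarity and likelihood computations
#'   require at least one taxon per sample).
#' @return the validated matrix with class `community_matrix` and attribute
#'   `is_counts`.
#' @export
community_matrix <- function(x, is_counts = NULL, require_positive_rows = TRUE) {
    x <- as.matrix(x)
    if (!is.numeric(x)) stop("community matrix must be numeric")
    if (anyNA(x)) stop("community matrix must not contain missing values")
    if (any(x < 0)) {
        bad <- which(x < 0, arr.ind = TRUE)[1, ]
        stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                     rownames(x)[bad[1]] %||% bad[1],
                     colnames(x)[bad[2]] %||% bad[2]))
    }
    if (is.null(rownames(x)) && nrow(x) > 0)
        rownames(x) <- paste0("sample", seq_len(nrow(x)))
    if (is.null(colnames(x)) && ncol(x) > 0)
        colnames(x) <- paste0("taxon", seq_len(ncol(x)))
    if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
    if (anyDuplicated(colnames(x))) stop("duplicate taxon ids")
    if (require_positive_rows && nrow(x) > 0 && ncol(x) > 0) {
        empty <- rownames(x)[rowSums(x) == 0]
        if (length(empty))
            stop("samples with no positive abundance: ",
                 paste(empty, collapse = ", "))
    }
    if (is.null(is_counts))
        is_counts <- length(x) == 0 || all(x == round(x))
    structure(x, class = c("community_matrix", class(x)),
              is_counts = isTRUE(is_counts))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

is_counts <- function(cm) isTRUE(attr(cm, "is_counts"))

#' @export
print.community_matrix <- function(x, ...) {
    cat(sprintf("community_matrix: %d samples x %d taxa (%s)\n",
                nrow(x), ncol(x),
                if (is_counts(x)) "counts" else "relative abundance"))
    print(head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]), ...)
    invisible(x)
}

#' Read a community matrix from a delimited file
#'
#' Expects a header row of taxon ids and one row per sample whose first column
#' is the sample id (taxa as rows is supported via `samples_as_rows = FALSE`).
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param samples_as_rows logical; set `FALSE` to transpose on read.
#' @param sep field separator; default guessed from the extension.
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path, samples_as_rows = TRUE, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE)
    ids <- as.character(raw[[1]])
    vals <- raw[, -1, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        if (anyNA(v) & !anyNA(vals[[j]])) {
            i <- which(is.na(v))[1]
            stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                         ids[i], colnames(vals)[j]))
        }
        vals[[j]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (!samples_as_rows) m <- t(m)
    community_matrix(m)
}

#' Write a community matrix to a delimited file
#'
#' @param cm a [community_matrix()].
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param sep optional explicit separator.
#' @export
write_community_matrix <- function(cm, path, sep = NULL) {
    sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(sample_id = rownames(cm), unclass(cm),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

land_use_classes <- c("arable", "improved grassland", "semi-natural grassland",
                      "woodland", "moorland", "bog")

#' Read a site table
#'
#' CSV with required columns `sample_id, site_id, x, y, layer, land_use`;
#' coordinates are planar metres (project geographic coordinates before use),
#' `layer` is the soil layer 1-4 and `land_use` one of the six vegetation
#' classes (arable, improved grassland, semi-natural grassland, woodland,
#' moorland, bog).
#'
#' @param path CSV path.
#' @return a validated data.frame.
#' @export
read_site_table <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    validate_site_table(df)
}

validate_site_table <- function(df) {
    req <- c("sample_id", "site_id", "x", "y", "layer", "land_use")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in site table")
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
        stop("site coordinates must be finite")
    if (!all(df$layer %in% 1:4)) stop("layer must be in 1..4")
    bad <- setdiff(unique(df$land_use), land_use_classes)
    if (length(bad)) stop("unknown land_use classes: ", paste(bad, collapse = ", "))
    df
}

#' Write a site table
#' @param sites site table data.frame.
#' @param path CSV output path.
#' @export
write_site_table <- function(sites, path) {
    write.csv(validate_site_table(sites), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a habitat (edaphic properties) matrix
#'
#' CSV whose first column is `sample_id` and remaining columns are numeric
#' habitat variables (missing values allowed).
#'
#' @param path CSV path.
#' @return numeric matrix with sample ids as row names, class
#'   `habitat_matrix`, attribute `standardized = FALSE`.
#' @export
read_habitat_table <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "sample_id") stop("first column must be sample_id")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df$sample_id)
    habitat_matrix(m, standardized = FALSE)
}

#' Construct a habitat matrix
#' @param m numeric samples x variables matrix (row names = sample ids).
#' @param standardized logical; `TRUE` if columns are already scaled to mean 0,
#'   unit variance.
#' @return classed matrix.
#' @export
habitat_matrix <- function(m, standardized = FALSE) {
    m <- as.matrix(m)
    if (anyDuplicated(colnames(m))) stop("duplicate habitat variable names")
    if (is.null(rownames(m))) stop("habitat matrix needs sample ids as row names")
    structure(m, class = c("habitat_matrix", class(m)),
              standardized = isTRUE(standardized))
}

#' Write a habitat matrix
#' @param hm habitat matrix.
#' @param path CSV output path.
#' @export
write_habitat_table <- function(hm, path) {
    df <- data.frame(sample_id = rownames(hm), unclass(hm),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Standardize habitat variables
#'
#' Centres and scales each column to mean 0 and unit variance over its
#' complete entries; zero-variance columns are dropped with a warning.
#'
#' @param hm habitat matrix.
#' @return standardized habitat matrix.
#' @export
standardize_habitat <- function(hm) {
    if (isTRUE(attr(hm, "standardized"))) return(hm)
    m <- unclass(hm)
    sds <- apply(m, 2, sd, na.rm = TRUE)
    zero <- !is.na(sds) & sds == 0
    if (any(zero)) {
        warning("dropping zero-variance habitat variables: ",
                paste(colnames(m)[zero], collapse = ", "))
        m <- m[, !zero, drop = FALSE]
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    habitat_matrix(m, standardized = TRUE)
}

#' Read a T-RFLP peak table
#'
#' CSV with columns `sample_id, fragment_size, height` (fragment sizes in base
#' pairs, heights in fluorescence units).
#'
#' @param path CSV path.
#' @return validated data.frame of class `peak_table`.
#' @export
read_peak_table <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    peak_table(df)
}

#' Construct a peak table
#' @param df data.frame with `sample_id`, `fragment_size`, `height`.
#' @return classed data.frame.
#' @export
peak_table <- function(df) {
    req <- c("sample_id", "fragment_size", "height")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("peak table missing columns: ", paste(miss, collapse = ", "))
    if (nrow(df) > 0) {
        if (any(!is.finite(df$fragment_size)) || any(df$fragment_size <= 0))
            stop("fragment_size must be positive")
        if (any(!is.finite(df$height)) || any(df$height < 0))
            stop("height must be non-negative")
    }
    class(df) <- c("peak_table", "data.frame")
    df
}

#' Write a peak table
#' @param peaks peak table.
#' @param path CSV output path.
#' @export
write_peak_table <- function(peaks, path) {
    write.csv(as.data.frame(peaks), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
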