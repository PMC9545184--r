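#' Read a TPS landmark file
#'
#' Parses the TPS format used by most landmark digitizing software. Records
#' begin with `LM=<p>` (2D) or `LM3=<p>` (3D) followed by one coordinate row
#' per landmark. `ID=` or `IMAGE=` fields are used as case ids (ID takes
#' precedence); `SCALE=<s>` is applied multiplicatively to the record's
#' coordinates. Unknown `KEY=value` lines are skipped with a warning. Line
#' endings (LF/CRLF) and trailing whitespace are tolerated.
#'
#' @param path path to a TPS file.
#' @return a [landmark_sample()].
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  configs <- list()
  ids <- character(0)
  cur <- NULL; cur_id <- NULL; cur_scale <- 1; dim_tag <- NULL; expect <- 0L

  flush_record <- function() {
    if (is.null(cur)) return(invisible())
    if (nrow(cur) != expect)
      stop("TPS format error: record declares ", expect,
           " landmarks but has ", nrow(cur))
    rec <- cur * cur_scale
    dimnames(rec) <- NULL
    configs[[length(configs) + 1L]] <<- rec
    ids[length(ids) + 1L] <<- if (is.null(cur_id)) as.character(length(ids) + 1L) else cur_id
    cur <<- NULL; cur_id <<- NULL; cur_scale <<- 1
  }

  for (ln in lines) {
    if (grepl("^(LM|LM3)\\s*=", ln, ignore.case = TRUE)) {
      flush_record()
      tag <- toupper(sub("\\s*=.*$", "", ln))
      if (is.null(dim_tag)) dim_tag <- tag
      if (tag != dim_tag)
        stop("TPS format error: mixed LM= and LM3= records in one file")
      expect <- as.integer(sub("^[^=]*=\\s*", "", ln))
      cur <- matrix(numeric(0), 0, if (tag == "LM3") 3 else 2)
    } else if (grepl("^[A-Za-z][A-Za-z0-9_]*\\s*=", ln)) {
      key <- toupper(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (key == "ID") cur_id <- val
      else if (key == "IMAGE") { if (is.null(cur_id)) cur_id <- val }
      else if (key == "SCALE") cur_scale <- as.numeric(val)
      else warning("ignoring unknown TPS key: ", key)
    } else {
      if (is.null(cur)) stop("TPS format error: coordinates before any LM= line")
      vals <- as.numeric(strsplit(ln, "\\s+")[[1]])
      if (length(vals) != ncol(cur))
        stop("TPS format error: expected ", ncol(cur),
             " coordinates per line, got ", length(vals))
      cur <- rbind(cur, vals)
    }
  }
  flush_record()
  if (length(configs) == 0L) stop("TPS format error: no LM= records found")
  ps <- vapply(configs, nrow, integer(1))
  if (any(ps != ps[1]))
    stop("TPS format error: inconsistent landmark counts across records (",
         paste(unique(ps), collapse = ", "), ")")
  landmark_sample(configs, ids = ids)
}

#' Write a TPS landmark file
#'
#' Emits one `LM=`/`LM3=` record per configuration with `ID=` fields and
#' fixed 6-decimal coordinate formatting, so `read_tps(write_tps(x))` round
#' trips coordinates to the emitted precision.
#'
#' @param sample a [landmark_sample()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  if (sample$n < 1L) stop("cannot write an empty sample")
  tag <- if (sample$k == 3L) "LM3=" else "LM="
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(sample$n)) {
    writeLines(paste0(tag, sample$p), con)
    m <- sample$coords[, , i]
    writeLines(apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines(paste0("ID=", sample$ids[i]), con)
  }
  invisible(path)
}

#' Read landmarks from a CSV table
#'
#' Two layouts are supported. `wide`: one row per specimen, an `id` column
#' plus `p*k` coordinate columns named `<landmark>_x`, `<landmark>_y`
#' (`_z` for 3D). `long`: one row per landmark with columns
#' `id`, `landmark`, `x`, `y`(, `z`).
#'
#' @param path path to a CSV file with a header.
#' @param layout `"wide"` or `"long"`.
#' @return a [landmark_sample()].
#' @export
read_landmark_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    idcol <- if ("id" %in% names(df)) "id" else names(df)[1]
    cc <- grep("_(x|y|z)$", names(df), value = TRUE)
    if (length(cc) == 0L) stop("no coordinate columns with _x/_y/_z suffixes found")
    k <- if (any(grepl("_z$", cc))) 3L else 2L
    lms <- unique(sub("_(x|y|z)$", "", cc))
    bad <- which(!vapply(df[cc], is.numeric, logical(1)) |
                 vapply(df[cc], anyNA, logical(1)))
    if (length(bad)) {
      cells <- unlist(lapply(cc[bad], function(col) {
        rows <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
        paste0("row ", rows, " column '", col, "'")
      }))
      stop("missing or non-numeric coordinates: ", paste(cells, collapse = "; "))
    }
    coords <- array(NA_real_, dim = c(length(lms), k, nrow(df)))
    axes <- c("x", "y", "z")[seq_len(k)]
    for (j in seq_along(lms)) for (a in seq_len(k)) {
      col <- paste0(lms[j], "_", axes[a])
      if (!col %in% names(df)) stop("missing coordinate column: ", col)
      coords[j, a, ] <- df[[col]]
    }
    landmark_sample(coords, ids = as.character(df[[idcol]]), landmark_names = lms)
  } else {
    need <- c("id", "landmark", "x", "y")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    k <- if ("z" %in% names(df)) 3L else 2L
    axes <- c("x", "y", "z")[seq_len(k)]
    na_rows <- which(rowSums(is.na(df[axes])) > 0)
    if (length(na_rows))
      stop("missing coordinates in rows: ", paste(na_rows, collapse = ", "))
    ids <- unique(as.character(df$id))
    lms <- unique(as.character(df$landmark))
    coords <- array(NA_real_, dim = c(length(lms), k, length(ids)))
    for (i in seq_along(ids)) {
      sub <- df[as.character(df$id) == ids[i], ]
      idx <- match(lms, as.character(sub$landmark))
      if (anyNA(idx)) stop("specimen ", ids[i], " is missing landmarks: ",
                           paste(lms[is.na(idx)], collapse = ", "))
      coords[, , i] <- as.matrix(sub[idx, axes])
    }
    landmark_sample(coords, ids = ids, landmark_names = lms)
  }
}

#' Write a landmark sample as a wide CSV
#'
#' @param sample a [landmark_sample()].
#' @param path output path.
#' @param extra optional data frame of extra columns (e.g. scores) bound
#'   after the coordinates.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(sample, path, extra = NULL) {
  stopifnot(inherits(sample, "landmark_sample"))
  wide <- as.data.frame(flatten_sample(sample$coords))
  out <- cbind(id = sample$ids, wide)
  if (!is.null(extra)) out <- cbind(out, extra)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Attach covariates to a landmark sample
#'
#' Joins a covariate table to the sample by case id; rows are re-ordered to
#' the sample's case order, so downstream row indices always refer to the
#' configuration order.
#'
#' @param sample a [landmark_sample()].
#' @param table a data frame with an `id` column and one row per case.
#' @return the sample with `$covariates` set.
#' @export
attach_covariates <- function(sample, table) {
  stopifnot(inherits(sample, "landmark_sample"), is.data.frame(table))
  if (!"id" %in% names(table)) stop("covariate table needs an 'id' column")
  tab_ids <- as.character(table$id)
  missing_ids <- setdiff(sample$ids, tab_ids)
  if (length(missing_ids))
    stop("covariate table is missing ids: ", paste(missing_ids, collapse = ", "))
  idx <- match(sample$ids, tab_ids)
  sample$covariates <- table[idx, , drop = FALSE]
  rownames(sample$covariates) <- NULL
  sample
}

#' Read a triangulated OBJ mesh
#'
#' Minimal Wavefront OBJ reader for `v` (vertex) and `f` (face) records;
#' texture/normal indices in face fields (`v/vt/vn`) are ignored, polygonal
#' faces are fan-triangulated. Intended for semilandmark projection, not for
#' general mesh processing.
#'
#' @param path path to an OBJ file.
#' @return a list with `vertices` (`v x 3` matrix) and `faces`
#'   (`f x 3` integer matrix of vertex indices), class `gm_mesh`.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ file has no vertices")
  verts <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vl), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*$", "", x))
    if (length(ix) < 3L) stop("OBJ face with fewer than 3 vertices")
    cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])  # fan triangulation
  }))
  if (!is.null(faces) && (min(faces) < 1L || max(faces) > nrow(verts)))
    stop("OBJ face indices out of range")
  structure(list(vertices = verts, faces = faces), class = "gm_mesh")
}
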