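#' Finite-element mesh
#'
#' Nodes plus solid (8-node hexahedral / 4-node tetrahedral) and shell
#' (3/4-node) elements with part IDs, and contact part pairs. Node and element
#' IDs are opaque integers and are never renumbered; morphing moves only the
#' coordinates.
#'
#' Solid connectivity is stored LS-DYNA style as an `n x 10` integer matrix
#' `(eid, pid, n1..n8)`, with tetrahedra carrying `n4` repeated in `n5..n8`;
#' `solid_nn` records the true node count (4 or 8). Shells are
#' `(eid, pid, n1..n4)` with triangles repeating `n3` in `n4`.
#'
#' @param node_ids integer vector of unique node IDs.
#' @param nodes `n x 3` numeric matrix of coordinates (mm), rows matching
#'   `node_ids`.
#' @param solids,shells connectivity matrices as described (node entries are
#'   node IDs, not row indices); may be `NULL`.
#' @param parts data frame with columns `pid`, `title` (optional).
#' @param contact_pairs integer matrix with two columns of part IDs, one row
#'   per declared contact.
#' @param extra_cards character vector of verbatim keyword lines carried
#'   through reads and writes so a morphed deck stays complete.
#' @return an object of class `fe_mesh`.
#' @export
fe_mesh <- function(node_ids, nodes, solids = NULL, shells = NULL,
                    parts = NULL, contact_pairs = NULL, extra_cards = NULL) {
  node_ids <- as.integer(node_ids)
  nodes <- as_points(nodes)
  if (anyDuplicated(node_ids)) stop("node IDs must be unique")
  if (length(node_ids) != nrow(nodes))
    stop("node_ids and nodes disagree in length")
  fix_solid <- function(m, width, name) {
    if (is.null(m) || nrow(m) == 0) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != width) stop(name, " matrix must have ", width, " columns")
    ref <- unique(as.vector(m[, -(1:2), drop = FALSE]))
    missing <- setdiff(ref, c(node_ids, 0L))
    if (length(missing) > 0)
      stop("elements reference missing node IDs: ",
           paste(head(missing, 10), collapse = ", "))
    m
  }
  solids <- fix_solid(solids, 10L, "solids")
  shells <- fix_solid(shells, 6L, "shells")
  if (is.null(parts)) {
    pids <- sort(unique(c(if (!is.null(solids)) solids[, 2],
                          if (!is.null(shells)) shells[, 2])))
    parts <- data.frame(pid = as.integer(pids),
                        title = paste0("part_", pids))
  }
  if (!is.null(contact_pairs)) {
    contact_pairs <- matrix(as.integer(contact_pairs), ncol = 2)
  }
  structure(list(node_ids = node_ids, nodes = nodes, solids = solids,
                 shells = shells, parts = parts,
                 contact_pairs = contact_pairs,
                 extra_cards = extra_cards),
            class = "fe_mesh")
}

solid_nn <- function(solids) {
  # tetrahedra carry n4 repeated in n5..n8 (columns 7:10 equal column 6)
  ifelse(solids[, 7] == solids[, 6] & solids[, 8] == solids[, 6] &
           solids[, 9] == solids[, 6] & solids[, 10] == solids[, 6], 4L, 8L)
}

n_solids <- function(mesh) if (is.null(mesh$solids)) 0L else nrow(mesh$solids)
n_shells <- function(mesh) if (is.null(mesh$shells)) 0L else nrow(mesh$shells)

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d solids, %d shells, %d parts\n",
              length(x$node_ids), n_solids(x), n_shells(x), nrow(x$parts)))
  if (!is.null(x$contact_pairs) && nrow(x$contact_pairs) > 0)
    cat(sprintf("  contact pairs: %s\n",
                paste(apply(x$contact_pairs, 1, paste, collapse = "-"),
                      collapse = ", ")))
  invisible(x)
}

node_index <- function(mesh, ids) {
  ix <- match(ids, mesh$node_ids)
  if (anyNA(ix)) stop("unknown node IDs")
  ix
}

#' Read a finite-element mesh
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension: `.k`/`.key`/`.dyn` keyword, `.vtk`
#'   legacy), `"lsdyna_keyword"` or `"vtk"`.
#' @return an [fe_mesh()].
#' @export
read_fe_mesh <- function(path, dialect = c("auto", "lsdyna_keyword", "vtk")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("k", "key", "dyn")) "lsdyna_keyword" else "vtk"
  }
  switch(dialect,
         lsdyna_keyword = read_lsdyna(path),
         vtk = read_vtk_mesh(path))
}

#' Write a finite-element mesh
#'
#' @param mesh an [fe_mesh()].
#' @inheritParams read_fe_mesh
#' @return `path`, invisibly.
#' @export
write_fe_mesh <- function(mesh, path,
                          dialect = c("auto", "lsdyna_keyword", "vtk")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("k", "key", "dyn")) "lsdyna_keyword" else "vtk"
  }
  switch(dialect,
         lsdyna_keyword = write_lsdyna(mesh, path),
         vtk = write_vtk_mesh(mesh, path))
  invisible(path)
}

# ---- LS-DYNA keyword subset -------------------------------------------------
# Supported cards: *NODE, *ELEMENT_SOLID (one-line form), *ELEMENT_SHELL,
# *PART (id/title), *CONTACT_... (first two integers of the first data line
# read as a part pair). Everything else is kept verbatim and re-emitted on
# write. Comment lines ($) are ignored; both comma-separated and
# fixed-width/whitespace fields are accepted.

split_fields <- function(line, widths) {
  if (grepl(",", line, fixed = TRUE)) {
    return(trimws(strsplit(line, ",", fixed = TRUE)[[1]]))
  }
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) >= 2) return(f)
  # fall back to fixed-width slicing
  starts <- cumsum(c(1, head(widths, -1)))
  ends <- cumsum(widths)
  out <- substring(line, starts, ends)
  trimws(out[nzchar(trimws(out))])
}

read_lsdyna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\$", txt)]
  is_kw <- grepl("^\\*", txt)
  if (!any(is_kw)) stop("not an LS-DYNA keyword file: ", path)
  kw_at <- which(is_kw)
  kw_name <- toupper(trimws(txt[kw_at]))
  blocks <- Map(function(s, e) if (s > e) character(0) else txt[s:e],
                kw_at + 1,
                c(kw_at[-1] - 1, length(txt)))

  nodes <- list(); solids <- list(); shells <- list()
  parts <- list(); contacts <- list(); extra <- character(0)
  for (b in seq_along(kw_name)) {
    kw <- kw_name[b]
    body <- blocks[[b]]
    body <- body[nzchar(trimws(body))]
    if (kw == "*NODE") {
      for (ln in body) {
        f <- split_fields(ln, c(8, 16, 16, 16))
        nodes[[length(nodes) + 1]] <- as.numeric(f[1:4])
      }
    } else if (startsWith(kw, "*ELEMENT_SOLID")) {
      for (ln in body) {
        f <- as.integer(split_fields(ln, rep(8, 10)))
        if (length(f) == 6) f <- c(f, rep(f[6], 4))  # 4-node tet short form
        if (length(f) < 10) f <- c(f, rep(f[length(f)], 10 - length(f)))
        solids[[length(solids) + 1]] <- f[1:10]
      }
    } else if (startsWith(kw, "*ELEMENT_SHELL")) {
      for (ln in body) {
        f <- as.integer(split_fields(ln, rep(8, 6)))
        if (length(f) == 5) f <- c(f, f[5])  # triangle short form
        shells[[length(shells) + 1]] <- f[1:6]
      }
    } else if (startsWith(kw, "*PART")) {
      # title line then id line
      if (length(body) >= 2) {
        id <- suppressWarnings(as.integer(split_fields(body[2], rep(10, 8))[1]))
        parts[[length(parts) + 1]] <- list(pid = id, title = trimws(body[1]))
      }
    } else if (startsWith(kw, "*CONTACT")) {
      if (length(body) >= 1) {
        f <- suppressWarnings(as.integer(split_fields(body[1], rep(10, 8))))
        if (length(f) >= 2 && !anyNA(f[1:2]))
          contacts[[length(contacts) + 1]] <- f[1:2]
      }
      extra <- c(extra, kw_name[b], blocks[[b]])
    } else if (!kw %in% c("*KEYWORD", "*END")) {
      extra <- c(extra, kw_name[b], blocks[[b]])
    }
  }
  if (length(nodes) == 0) stop("keyword file has no *NODE block: ", path)
  if (length(solids) == 0 && length(shells) == 0)
    stop("keyword file has no *ELEMENT_SOLID or *ELEMENT_SHELL block: ", path)
  nm <- do.call(rbind, nodes)
  sm <- if (length(solids)) do.call(rbind, solids) else NULL
  hm <- if (length(shells)) do.call(rbind, shells) else NULL
  pdf <- if (length(parts))
    data.frame(pid = vapply(parts, `[[`, integer(1), "pid"),
               title = vapply(parts, `[[`, character(1), "title"))
  else NULL
  cm <- if (length(contacts)) do.call(rbind, contacts) else NULL
  ref <- unique(c(if (!is.null(sm)) as.vector(sm[, 3:10]),
                  if (!is.null(hm)) as.vector(hm[, 3:6])))
  missing <- setdiff(ref, c(as.integer(nm[, 1]), 0L))
  if (length(missing) > 0)
    stop("mesh integrity error: elements reference missing node IDs: ",
         paste(head(sort(missing), 10), collapse = ", "))
  fe_mesh(node_ids = as.integer(nm[, 1]), nodes = nm[, 2:4, drop = FALSE],
          solids = sm, shells = hm, parts = pdf, contact_pairs = cm,
          extra_cards = if (length(extra)) extra else NULL)
}

write_lsdyna <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*KEYWORD", con)
  if (!is.null(mesh$parts)) {
    for (r in seq_len(nrow(mesh$parts))) {
      writeLines("*PART", con)
      writeLines(as.character(mesh$parts$title[r]), con)
      writeLines(formatC(mesh$parts$pid[r], width = 10), con)
    }
  }
  writeLines("*NODE", con)
  writeLines(sprintf("%8d%16.8g%16.8g%16.8g", mesh$node_ids,
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  if (!is.null(mesh$solids)) {
    writeLines("*ELEMENT_SOLID", con)
    s <- mesh$solids
    writeLines(sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d%8d", s[, 1], s[, 2],
                       s[, 3], s[, 4], s[, 5], s[, 6], s[, 7], s[, 8],
                       s[, 9], s[, 10]), con)
  }
  if (!is.null(mesh$shells)) {
    writeLines("*ELEMENT_SHELL", con)
    s <- mesh$shells
    writeLines(sprintf("%8d%8d%8d%8d%8d%8d", s[, 1], s[, 2], s[, 3], s[, 4],
                       s[, 5], s[, 6]), con)
  }
  has_contact_card <- !is.null(mesh$extra_cards) &&
    any(startsWith(toupper(trimws(mesh$extra_cards)), "*CONTACT"))
  if (!is.null(mesh$contact_pairs) && nrow(mesh$contact_pairs) > 0 &&
      !has_contact_card) {
    for (r in seq_len(nrow(mesh$contact_pairs))) {
      writeLines("*CONTACT_AUTOMATIC_SURFACE_TO_SURFACE", con)
      writeLines(sprintf("%10d%10d%10d%10d", mesh$contact_pairs[r, 1],
                         mesh$contact_pairs[r, 2], 3L, 3L), con)
    }
  }
  if (!is.null(mesh$extra_cards)) writeLines(mesh$extra_cards, con)
  writeLines("*END", con)
  invisible(path)
}

# ---- legacy VTK unstructured grid ------------------------------------------

read_vtk_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (length(ip) != 1) stop("not a legacy VTK unstructured grid: ", path)
  npts <- as.integer(strsplit(trimws(txt[ip]), "\\s+")[[1]][2])
  nums <- scan(text = paste(txt[(ip + 1):length(txt)], collapse = "\n"),
               what = numeric(), n = 3 * npts, quiet = TRUE)
  pts <- matrix(nums, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", txt)
  hdr <- strsplit(trimws(txt[ic[1]]), "\\s+")[[1]]
  ncell <- as.integer(hdr[2]); ntot <- as.integer(hdr[3])
  cvals <- scan(text = paste(txt[(ic[1] + 1):length(txt)], collapse = "\n"),
                what = integer(), n = ntot, quiet = TRUE)
  it <- grep("^CELL_TYPES", txt)
  ctypes <- scan(text = paste(txt[(it[1] + 1):length(txt)], collapse = "\n"),
                 what = integer(), n = ncell, quiet = TRUE)
  # per-cell data arrays (part_id, element_id) if present
  read_cell_scalar <- function(name) {
    isc <- grep(paste0("^SCALARS\\s+", name), txt)
    if (length(isc) == 0) return(NULL)
    scan(text = paste(txt[(isc[1] + 2):length(txt)], collapse = "\n"),
         what = integer(), n = ncell, quiet = TRUE)
  }
  pid <- read_cell_scalar("part_id")
  eid <- read_cell_scalar("element_id")
  if (is.null(pid)) pid <- rep(1L, ncell)
  if (is.null(eid)) eid <- seq_len(ncell)

  solids <- list(); shells <- list()
  pos <- 1L
  for (cidx in seq_len(ncell)) {
    n <- cvals[pos]
    conn <- cvals[(pos + 1):(pos + n)] + 1L  # VTK is 0-based
    pos <- pos + n + 1L
    ty <- ctypes[cidx]
    if (ty == 12L) {         # hexahedron
      solids[[length(solids) + 1]] <- c(eid[cidx], pid[cidx], conn)
    } else if (ty == 10L) {  # tetrahedron
      solids[[length(solids) + 1]] <-
        c(eid[cidx], pid[cidx], conn, rep(conn[4], 4))
    } else if (ty == 9L) {   # quad
      shells[[length(shells) + 1]] <- c(eid[cidx], pid[cidx], conn)
    } else if (ty == 5L) {   # triangle
      shells[[length(shells) + 1]] <- c(eid[cidx], pid[cidx], conn, conn[3])
    } else stop("unsupported VTK cell type: ", ty)
  }
  fe_mesh(node_ids = seq_len(npts), nodes = pts,
          solids = if (length(solids)) do.call(rbind, solids) else NULL,
          shells = if (length(shells)) do.call(rbind, shells) else NULL)
}

write_vtk_mesh <- function(mesh, path) {
  # VTK addresses points 0..n-1, so connectivity is written as row indices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "morphforge mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", length(mesh$node_ids))), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  cells <- character(0); types <- integer(0); pids <- integer(0)
  eids <- integer(0); ntot <- 0L
  if (!is.null(mesh$solids)) {
    nn <- solid_nn(mesh$solids)
    for (r in seq_len(nrow(mesh$solids))) {
      conn <- node_index(mesh, mesh$solids[r, 3:(2 + nn[r])]) - 1L
      cells <- c(cells, paste(c(nn[r], conn), collapse = " "))
      types <- c(types, if (nn[r] == 8L) 12L else 10L)
      pids <- c(pids, mesh$solids[r, 2]); eids <- c(eids, mesh$solids[r, 1])
      ntot <- ntot + nn[r] + 1L
    }
  }
  if (!is.null(mesh$shells)) {
    tri <- mesh$shells[, 6] == mesh$shells[, 5]
    for (r in seq_len(nrow(mesh$shells))) {
      nn <- if (tri[r]) 3L else 4L
      conn <- node_index(mesh, mesh$shells[r, 3:(2 + nn)]) - 1L
      cells <- c(cells, paste(c(nn, conn), collapse = " "))
      types <- c(types, if (nn == 4L) 9L else 5L)
      pids <- c(pids, mesh$shells[r, 2]); eids <- c(eids, mesh$shells[r, 1])
      ntot <- ntot + nn + 1L
    }
  }
  writeLines(sprintf("CELLS %d %d", length(types), ntot), con)
  writeLines(cells, con)
  writeLines(sprintf("CELL_TYPES %d", length(types)), con)
  writeLines(as.character(types), con)
  writeLines(sprintf("CELL_DATA %d", length(types)), con)
  writeLines(c("SCALARS part_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(pids), con)
  writeLines(c("SCALARS element_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(eids), con)
  invisible(path)
}
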