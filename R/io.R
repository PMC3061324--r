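# Readers and writers for the plain-text formats: .tri meshes, .geom/.cond
# head descriptions, ASCII matrices and sensor/dipole tables. All geometric
# quantities are in SI units (meters, S/m, A m).

#' Read and write surface meshes in the .tri dialect
#'
#' Format: a line `- N`, then N lines `x y z nx ny nz` (vertex position and
#' vertex normal), a line `- M M M`, then M lines of 0-based triangle indices.
#' The reader validates counts, index ranges and finiteness; the writer emits
#' area-weighted vertex normals and round-trips the vertex/triangle arrays.
#'
#' @param path file path.
#' @return a `bem_mesh`.
#' @export
read_tri <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "-" || length(hdr) < 2)
    stop("malformed .tri header (expected '- N'): ", lines[1])
  nv <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(nv) || nv < 3) stop("malformed vertex count in .tri header: ", hdr[2])
  if (length(lines) < 1 + nv + 1) stop("truncated .tri file: missing vertices")
  vt <- do.call(rbind, lapply(lines[2:(1 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(vt) < 3) stop("vertex lines need at least x y z")
  if (!all(is.finite(vt[, 1:3]))) stop("non-finite vertex coordinate in .tri")
  thdr <- strsplit(trimws(lines[2 + nv]), "\\s+")[[1]]
  if (thdr[1] != "-") stop("malformed .tri triangle header: ", lines[2 + nv])
  nt <- suppressWarnings(as.integer(thdr[2]))
  if (is.na(nt) || nt < 1) stop("malformed triangle count: ", lines[2 + nv])
  if (length(lines) < 2 + nv + nt) stop("truncated .tri file: missing triangles")
  tr <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nt)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  if (any(is.na(tr))) stop("malformed triangle line in .tri")
  if (any(tr < 0) || any(tr >= nv))
    stop("triangle index out of range [0, ", nv - 1, "] in .tri")
  triangle_mesh(vt[, 1:3, drop = FALSE], tr + 1L)
}

#' @rdname read_tri
#' @param mesh a `bem_mesh` to write.
#' @export
write_tri <- function(mesh, path) {
  nv <- n_vertices(mesh); nt <- n_triangles(mesh)
  # area-weighted vertex normals
  vn <- matrix(0, nv, 3)
  f <- mesh$triangles
  for (j in 1:3) {
    w <- mesh$normals * mesh$areas
    vn[, 1] <- vn[, 1] + tabulate_sum(f[, j], w[, 1], nv)
    vn[, 2] <- vn[, 2] + tabulate_sum(f[, j], w[, 2], nv)
    vn[, 3] <- vn[, 3] + tabulate_sum(f[, j], w[, 3], nv)
  }
  nrm <- pmax(sqrt(rowSums(vn^2)), 1e-300)
  vn <- vn / nrm
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("- %d", nv), con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                     vn[, 1], vn[, 2], vn[, 3]), con)
  writeLines(sprintf("- %d %d %d", nt, nt, nt), con)
  writeLines(sprintf("%d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Read a geometry (.geom) + conductivity (.cond) pair into a head model
#'
#' Minimal versioned dialect. Geometry file:
#' \preformatted{
#' # bem geometry 1.0
#' Interfaces 3
#' Brain brain.tri
#' Skull skull.tri
#' Scalp scalp.tri
#' Domains 4
#' Brain inside Brain
#' SkullD outside Brain inside Skull
#' ScalpD outside Skull inside Scalp
#' Air outside Scalp
#' }
#' Interfaces are listed innermost first (verified against the winding-number
#' nesting check; a shuffled order is reordered when unambiguous). The
#' conductivity file lists `DomainName value` pairs (S/m); every non-exterior
#' domain must have one. Coordinates are in meters: a unit sanity warning is
#' emitted when the scalp bounding radius exceeds 1 m.
#'
#' @param geom_path path to the .geom file.
#' @param cond_path path to the .cond file.
#' @return a `bem_head_model`.
#' @export
read_geom <- function(geom_path, cond_path) {
  lines <- trimws(readLines(geom_path))
  lines <- lines[nzchar(lines)]
  if (!grepl("^#\\s*bem geometry 1\\.0", lines[1]))
    stop("missing or unsupported .geom header (expected '# bem geometry 1.0')")
  lines <- lines[-1]
  ih <- grep("^Interfaces\\b", lines)
  dh <- grep("^Domains\\b", lines)
  if (length(ih) != 1 || length(dh) != 1) stop("need one Interfaces and one Domains section")
  n_if <- as.integer(strsplit(lines[ih], "\\s+")[[1]][2])
  if_lines <- lines[(ih + 1):(ih + n_if)]
  ifaces <- do.call(rbind, lapply(if_lines, function(l) {
    p <- strsplit(l, "\\s+")[[1]]
    if (length(p) != 2) stop("interface line must be 'Name path': ", l)
    data.frame(name = p[1], path = p[2])
  }))
  n_dom <- as.integer(strsplit(lines[dh], "\\s+")[[1]][2])
  dom_lines <- lines[(dh + 1):(dh + n_dom)]
  domains <- lapply(dom_lines, function(l) {
    p <- strsplit(l, "\\s+")[[1]]
    name <- p[1]; rest <- p[-1]
    if (length(rest) %% 2 != 0) stop("malformed domain line: ", l)
    rel <- rest[seq(1, length(rest), 2)]
    tgt <- rest[seq(2, length(rest), 2)]
    if (!all(rel %in% c("inside", "outside")))
      stop("domain memberships must be 'inside'/'outside': ", l)
    if (!all(tgt %in% ifaces$name))
      stop("unknown interface in domain line: ", l)
    list(name = name, rel = rel, tgt = tgt)
  })
  meshes <- lapply(file.path(dirname(geom_path), ifaces$path), read_tri)
  names(meshes) <- ifaces$name
  # order innermost-first by enclosed volume, verify by nesting check
  vols <- vapply(meshes, mesh_volume, numeric(1))
  ord <- order(vols)
  meshes <- meshes[ord]
  # conductivities by domain name: the domain 'inside X and outside X-1' gets
  # the slot of interface X; the exterior domain (outside the outermost only)
  # is fixed at 0 and needs no entry
  cl <- trimws(readLines(cond_path))
  cl <- cl[nzchar(cl) & !grepl("^#", cl)]
  cond_tab <- do.call(rbind, lapply(cl, function(l) {
    p <- strsplit(l, "\\s+")[[1]]
    data.frame(domain = p[1], value = as.numeric(p[2]))
  }))
  sigma <- rep(NA_real_, length(meshes))
  outer_name <- names(meshes)[length(meshes)]
  for (d in domains) {
    ins <- d$tgt[d$rel == "inside"]
    if (length(ins) == 0) next # exterior domain
    # innermost enclosing interface defines the slot
    slot <- min(match(ins, names(meshes)))
    val <- cond_tab$value[cond_tab$domain == d$name]
    if (length(val) != 1 || is.na(val))
      stop("conductivity file is missing domain \"", d$name, "\"")
    sigma[slot] <- val
  }
  if (anyNA(sigma))
    stop("no conductivity resolved for interface(s): ",
         paste(names(meshes)[is.na(sigma)], collapse = ", "))
  rmax <- max(sqrt(rowSums(meshes[[length(meshes)]]$vertices^2)))
  if (rmax > 1)
    warning(sprintf(paste0("scalp bounding radius is %.3g m; coordinates are ",
                           "expected in meters"), rmax))
  head_model(unname(meshes), sigma, names = names(meshes))
}

#' ASCII matrix format
#'
#' Header line `rows cols` (plus the word `symmetric` for symmetric matrices),
#' followed by whitespace-separated values; symmetric matrices store the lower
#' triangle row by row. Full precision (17 significant digits) round-trips
#' doubles exactly.
#'
#' @param M numeric matrix.
#' @param path file path.
#' @param symmetric store only the lower triangle.
#' @export
write_matrix_ascii <- function(M, path, symmetric = FALSE) {
  M <- as.matrix(M)
  con <- file(path, "w"); on.exit(close(con))
  if (symmetric) {
    if (nrow(M) != ncol(M) || !isTRUE(all.equal(M, t(M), tolerance = 1e-10)))
      stop("matrix is not symmetric")
    writeLines(sprintf("%d %d symmetric", nrow(M), ncol(M)), con)
    for (i in seq_len(nrow(M)))
      writeLines(paste(sprintf("%.17g", M[i, 1:i]), collapse = " "), con)
  } else {
    writeLines(sprintf("%d %d", nrow(M), ncol(M)), con)
    for (i in seq_len(nrow(M)))
      writeLines(paste(sprintf("%.17g", M[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_matrix_ascii
#' @export
read_matrix_ascii <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  if (is.na(nr) || is.na(nc)) stop("malformed matrix header: ", lines[1])
  sym <- length(hdr) >= 3 && hdr[3] == "symmetric"
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
  if (sym) {
    if (nr != nc) stop("symmetric matrix must be square")
    if (length(vals) != nr * (nr + 1) / 2)
      stop("expected ", nr * (nr + 1) / 2, " lower-triangle values, got ",
           length(vals))
    M <- matrix(0, nr, nc)
    k <- 0L
    for (i in seq_len(nr)) {
      M[i, 1:i] <- vals[(k + 1):(k + i)]
      k <- k + i
    }
    M <- M + t(M) - diag(diag(M))
  } else {
    if (length(vals) != nr * nc)
      stop("expected ", nr * nc, " values, got ", length(vals))
    M <- matrix(vals, nr, nc, byrow = TRUE)
  }
  M
}

parse_numeric_table <- function(path, what = "input") {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty ", what, " file: ", path)
  lapply(seq_along(lines), function(i) {
    p <- strsplit(lines[i], "\\s+")[[1]]
    list(row = i, fields = p)
  })
}

#' Read plain-text dipole and sensor descriptions
#'
#' Dipoles: rows `x y z qx qy qz`. Point sensors (EEG/EIT/IP): rows
#' `[name] x y z` (leading name optional). MEG sensors: rows
#' `x y z dx dy dz [weight] [channel]`; rows sharing a channel label form one
#' channel with several weighted integration points (default weight 1, default
#' channel = row number). Malformed rows are reported with their row number.
#'
#' @param path file path.
#' @return `read_dipoles_txt`: list with `positions`, `moments`;
#'   `read_points_txt`: list with `positions`, `names`;
#'   `read_meg_txt`: a `bem_sensors` of kind "MEG".
#' @export
read_dipoles_txt <- function(path) {
  rows <- parse_numeric_table(path, "dipole")
  tab <- do.call(rbind, lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r$fields))
    if (length(v) != 6 || anyNA(v))
      stop("dipole row ", r$row, " must have 6 numeric fields (x y z qx qy qz)")
    v
  }))
  list(positions = tab[, 1:3, drop = FALSE], moments = tab[, 4:6, drop = FALSE])
}

#' @rdname read_dipoles_txt
#' @export
read_points_txt <- function(path) {
  rows <- parse_numeric_table(path, "points")
  nm <- character(length(rows))
  pos <- matrix(0, length(rows), 3)
  for (r in rows) {
    f <- r$fields
    v <- suppressWarnings(as.numeric(f))
    if (length(f) == 4 && is.na(v[1])) {
      nm[r$row] <- f[1]; v <- v[-1]
    } else nm[r$row] <- paste0("P", r$row)
    if (length(v) != 3 || anyNA(v))
      stop("point row ", r$row, " must be '[name] x y z'")
    pos[r$row, ] <- v
  }
  list(positions = pos, names = nm)
}

#' @rdname read_dipoles_txt
#' @export
read_meg_txt <- function(path) {
  rows <- parse_numeric_table(path, "MEG sensor")
  pts <- dirs <- NULL; w <- numeric(0); ch <- character(0)
  for (r in rows) {
    f <- r$fields
    v <- suppressWarnings(as.numeric(f))
    if (length(f) < 6 || anyNA(v[1:6]))
      stop("MEG row ", r$row, " must start with 6 numeric fields (x y z dx dy dz)")
    pts <- rbind(pts, v[1:6][1:3]); dirs <- rbind(dirs, v[4:6])
    w <- c(w, if (length(f) >= 7 && !is.na(v[7])) v[7] else 1)
    ch <- c(ch, if (length(f) >= 8) f[8] else as.character(r$row))
  }
  meg_sensors(pts, dirs, weights = w, channels = ch)
}

#' @rdname read_geom
#' @param model a `bem_head_model` to write.
#' @param dir output directory (created if needed).
#' @param stem base name for the emitted files.
#' @return invisibly, the paths written (geom, cond, tri files).
#' @export
write_geom <- function(model, dir, stem = "head") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- length(model$interfaces)
  tri_paths <- sprintf("%s_%d.tri", stem, seq_len(N))
  for (i in seq_len(N)) write_tri(model$interfaces[[i]], file.path(dir, tri_paths[i]))
  geom <- file.path(dir, paste0(stem, ".geom"))
  cond <- file.path(dir, paste0(stem, ".cond"))
  nm <- model$names
  gl <- c("# bem geometry 1.0",
          sprintf("Interfaces %d", N),
          sprintf("%s %s", nm, tri_paths),
          sprintf("Domains %d", N + 1))
  dn <- paste0("Domain", seq_len(N))
  for (i in seq_len(N)) {
    rel <- sprintf("inside %s", nm[i])
    if (i > 1) rel <- paste(sprintf("outside %s", nm[i - 1]), rel)
    gl <- c(gl, sprintf("%s %s", dn[i], rel))
  }
  gl <- c(gl, sprintf("Air outside %s", nm[N]))
  writeLines(gl, geom)
  writeLines(c("# bem conductivity 1.0",
               sprintf("%s %.17g", dn, model$conductivities)), cond)
  invisible(list(geom = geom, cond = cond,
                 tri = file.path(dir, tri_paths)))
}
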