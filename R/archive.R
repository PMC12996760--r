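ARCHIVE_FORMAT <- "thc-correct/1"

#' Write a system archive
#'
#' Serializes one species — orbital data, density-fitting factors and parent
#' collocation grids — into a self-contained HDF5 file with groups
#' `/orbitals`, `/df`, `/grid/{oo,ov,vv}` and `/meta`. Existing files are
#' overwritten. All arrays round-trip bit-exactly through
#' [read_system_archive()].
#'
#' @param system an [orbital_system()].
#' @param df a [df_tensors()].
#' @param grids named list of [collocation()] objects with names
#'   `oo`, `ov`, `vv`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_system_archive <- function(system, df, grids, path) {
  validate_orbital_system(system)
  validate_df_tensors(df)
  if (!all(c("oo", "ov", "vv") %in% names(grids)))
    stop("write_system_archive: grids must contain oo, ov and vv collocations")
  for (pt in c("oo", "ov", "vv")) {
    validate_collocation(grids[[pt]])
    if (grids[[pt]]$pair_type != pt)
      stop(sprintf("write_system_archive: grids[['%s']] has pair_type '%s'",
                   pt, grids[[pt]]$pair_type))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- function(obj, name) rhdf5::h5write(obj, path, name)

  rhdf5::h5createGroup(path, "meta")
  h5(ARCHIVE_FORMAT, "meta/format")
  h5(system$species_id, "meta/species_id")

  rhdf5::h5createGroup(path, "orbitals")
  h5(system$eps, "orbitals/eps")
  h5(system$n_occ_active, "orbitals/n_occ_active")
  h5(system$n_vir, "orbitals/n_vir")
  h5(system$n_frozen, "orbitals/n_frozen")
  h5(system$n_valence, "orbitals/n_valence")
  h5(system$e_scf, "orbitals/e_scf")

  rhdf5::h5createGroup(path, "df")
  h5(df$B_oo, "df/B_oo")
  h5(df$B_ov, "df/B_ov")
  h5(df$B_vv, "df/B_vv")

  rhdf5::h5createGroup(path, "grid")
  for (pt in c("oo", "ov", "vv")) {
    g <- grids[[pt]]
    grp <- paste0("grid/", pt)
    rhdf5::h5createGroup(path, grp)
    h5(g$X_left, paste0(grp, "/X_left"))
    h5(g$X_right, paste0(grp, "/X_right"))
    if (!is.null(g$grid_coords)) h5(g$grid_coords, paste0(grp, "/coords"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a system archive
#'
#' @param path an HDF5 file written by [write_system_archive()].
#' @return a list with elements `system`, `df`, `grids`.
#' @export
read_system_archive <- function(path) {
  if (!file.exists(path)) stop("read_system_archive: no such file: ", path)
  fmt <- as.character(rhdf5::h5read(path, "meta/format"))
  if (!identical(fmt, ARCHIVE_FORMAT))
    stop("read_system_archive: unsupported format: ", fmt)
  rd <- function(name) rhdf5::h5read(path, name)
  sys <- orbital_system(
    species_id = as.character(rd("meta/species_id")),
    eps = as.numeric(rd("orbitals/eps")),
    n_occ_active = as.integer(rd("orbitals/n_occ_active")),
    n_vir = as.integer(rd("orbitals/n_vir")),
    n_frozen = as.integer(rd("orbitals/n_frozen")),
    e_scf = as.numeric(rd("orbitals/e_scf"))
  )
  df <- df_tensors(rd("df/B_oo"), rd("df/B_ov"), rd("df/B_vv"))
  contents <- rhdf5::h5ls(path)
  grids <- list()
  for (pt in c("oo", "ov", "vv")) {
    grp <- paste0("/grid/", pt)
    has_coords <- any(contents$group == grp & contents$name == "coords")
    grids[[pt]] <- collocation(
      pt,
      as.matrix(rd(paste0("grid/", pt, "/X_left"))),
      as.matrix(rd(paste0("grid/", pt, "/X_right"))),
      grid_coords = if (has_coords) as.matrix(rd(paste0("grid/", pt, "/coords")))
    )
  }
  rhdf5::h5closeAll()
  list(system = sys, df = df, grids = grids)
}

#' Read reaction schemes from CSV
#'
#' The carrier format is a headered CSV with columns
#' `reaction_id,species_id,nu`; rows are grouped by `reaction_id` in order of
#' first appearance, member order preserved. Products have positive `nu`,
#' reactants negative.
#'
#' @param path CSV file path.
#' @return list of [reaction_scheme()] objects.
#' @export
read_reactions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("reaction_id", "species_id", "nu")
  if (!identical(sort(names(tab)), sort(need)))
    stop("read_reactions: header must be exactly reaction_id,species_id,nu (got: ",
         paste(names(tab), collapse = ","), ")")
  nu_num <- suppressWarnings(as.numeric(tab$nu))
  bad <- which(!is.finite(nu_num) | nu_num != round(nu_num))
  if (length(bad))
    stop(sprintf("read_reactions: non-integer nu at data row %d (file line %d)",
                 bad[1], bad[1] + 1L))
  ids <- unique(tab$reaction_id)
  lapply(ids, function(id) {
    rows <- which(tab$reaction_id == id)
    tryCatch(
      reaction_scheme(id, tab$species_id[rows], as.integer(nu_num[rows])),
      error = function(e) stop(sprintf(
        "read_reactions: scheme '%s' (first at file line %d): %s",
        id, rows[1] + 1L, conditionMessage(e)), call. = FALSE)
    )
  })
}

#' Write reaction schemes to CSV
#'
#' @param schemes list of [reaction_scheme()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(schemes, path) {
  tab <- do.call(rbind, lapply(schemes, function(s)
    data.frame(reaction_id = s$reaction_id, species_id = s$species_id,
               nu = s$nu, stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
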