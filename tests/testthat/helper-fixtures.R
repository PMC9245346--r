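# Shared fixtures. Heavy objects (phantoms, field solutions) are memoized in
# a session cache so independent test files can reuse them without re-solving.

.ttcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ttcache))
    assign(key, force(expr), envir = .ttcache)
  get(key, envir = .ttcache)
}

# A reduced head (thicker shells) that stays resolvable at 4 mm voxels,
# for cheap solves in unit tests.
coarse_geom <- function() {
  head_geometry(outer_semiaxes_mm = c(80, 95, 88),
                scalp_mm = 6, skull_mm = 7, csf_mm = 4, gm_mm = 5)
}

coarse_phantom <- function() cached("coarse_phantom", {
  insert_pathology(build_head_phantom(coarse_geom(), 4))
})

# Study-resolution (3 mm) fixtures used by the acceptance criteria.
study_base <- function() cached("study_base", {
  insert_pathology(build_head_phantom(head_geometry(), 3))
})

study_vol <- function(variant) cached(paste0("study_vol_", variant), {
  base <- study_base()
  apply_sr_surgery(base, place_quincunx(base, variant))
})

study_cv <- function(variant) cached(paste0("study_cv_", variant), {
  assign_conductivities(study_vol(variant))
})

study_regions <- function() cached("study_regions", {
  derive_regions(study_base())
})

# Memoized field solve on the study phantom for (variant, family, parameter).
study_solve <- function(variant, family = "circumferential", parameter = 60) {
  key <- sprintf("sol_%s_%s_%g", variant, family, parameter)
  cached(key, {
    geom <- head_geometry()
    pair <- switch(family,
      circumferential = layout_circumferential(geom, parameter),
      normal_rotation = layout_normal_rotation(geom, parameter),
      vertex_translation = layout_vertex_translation(geom, parameter))
    solve_fields(study_cv(variant), pair)
  })
}

# 6-connected component count of a logical 3-D mask (small masks only).
n_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- stats::setNames(seq_len(n), key)
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (d in 1:3) for (o in c(-1L, 1L)) {
        nb <- idx[v, ]; nb[d] <- nb[d] + o
        j <- lookup[paste(nb[1], nb[2], nb[3])]
        if (!is.na(j) && comp[j] == 0) { comp[j] <- nc; queue <- c(queue, j) }
      }
    }
  }
  nc
}
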