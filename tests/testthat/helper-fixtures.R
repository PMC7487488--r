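# Shared fixtures, built lazily and cached for the session so expensive
# objects (the end-to-end demo volunteer) are computed once.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# Small all-inside voxel block converted to tets; labels all cortical.
block_model <- function(dims = c(2, 2, 10), h = 1, template = "kuhn6",
                        E = 1000, nu = 0) {
  g <- wbafem:::voxel_tet_grid(function(p) rep(TRUE, nrow(p)),
                               c(0, 0, 0), dims, h, template)
  tet_model(g$nodes, g$elements, rep("cortical", nrow(g$elements)),
            node_sets = list(distal_fixed = which(g$nodes[, 3] < 1e-9)))
}

# Tributary-area nodal forces equivalent to a uniform traction on the top
# face (z = height) of a block model.
top_traction_forces <- function(model, height, traction = c(0, 0, 1)) {
  bf <- wbafem:::boundary_faces(model)
  top <- bf$centroids[, 3] > height - 1e-9
  f <- matrix(0, nrow(model$nodes), 3)
  for (cx in 1:3) {
    acc <- tapply(bf$areas[top] / 3, bf$faces[top, cx], sum)
    ids <- as.integer(names(acc))
    f[ids, ] <- f[ids, ] + outer(as.numeric(acc), traction)
  }
  f
}

# The packaged synthetic volunteer run end-to-end (fixture + full pipeline),
# shared by the pipeline and acceptance tests.
demo_run <- function() {
  cache_fixture("demo_run", function() {
    dir <- file.path(tempdir(), "wbafem-demo-shared")
    fx <- make_demo_fixture(dir, seed = 7L)
    cfg <- fx$config
    cfg$log_level <- "quiet"
    res <- run_pipeline(cfg)
    list(fixture = fx, result = res)
  })
}

# A fitted unit-sphere head model at the given tessellation.
unit_sphere_head <- function(n_lat = 110L, n_lon = 100L) {
  mesh <- uv_sphere_mesh(radius = 1, n_lat = n_lat, n_lon = n_lon)
  fit_head_sphere(mesh, hint = seq_len(nrow(mesh$vertices)))
}
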