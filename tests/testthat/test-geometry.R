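test_that("geometry invariants hold and bad inputs are rejected", {
  g <- geometry_params(d_cap = 5e-5, r = 2.5e-6)
  expect_equal(g$x_r, g$d_cap + 2 * g$r)
  expect_equal(g$x_r, g$y_r)
  expect_equal(g$x_r, 5.5e-5)
  # r < x_r/2 is implied by d_cap > 0; degenerate inputs are rejected
  expect_error(geometry_params(d_cap = 0, r = 1e-6))
  expect_error(geometry_params(d_cap = -1, r = 1e-6))
  expect_error(geometry_params(d_cap = 5e-5, r = 0))
})

test_that("classify_point reproduces the published subdomain examples", {
  g <- geometry_params()
  xr <- g$x_r; r <- g$r
  expect_equal(as.character(classify_point(xr / 2, r / 2, r / 2, g)), "PL_X1")
  expect_equal(as.character(classify_point(xr / 2, xr / 2, xr / 2, g)), "ECF")
  expect_equal(as.character(classify_point(r / 2, r / 2, r / 2, g)), "PL_IN")
  expect_equal(as.character(classify_point(xr - r / 2, xr - r / 2, xr - r / 2, g)),
               "PL_OUT")
  # interface points: on the capillary boundary but not on the cube surface
  expect_equal(as.character(classify_point(r, r, xr / 2, g)), "BBB")
  expect_equal(as.character(classify_point(xr / 2, r, r / 2, g)), "BBB")
  expect_error(classify_point(-1e-9, 0, 0, g), class = "bu_domain_error")
})

test_that("classification is a total partition of the closed cube", {
  g <- geometry_params()
  set.seed(42)
  n <- 1e5
  pts <- matrix(runif(3 * n, 0, g$x_r), ncol = 3)
  lab <- classify_point(pts[, 1], pts[, 2], pts[, 3], g)
  expect_false(anyNA(lab))
  expect_equal(length(lab), n)
  # plasma volume fraction of the box model: (12 d_cap r^2 + 8 r^3) / x_r^3
  frac_pl <- mean(lab != "ECF" & lab != "BBB")
  frac_exact <- (12 * g$d_cap * g$r^2 + 8 * g$r^3) / g$x_r^3
  expect_lt(abs(frac_pl - frac_exact) / frac_exact, 0.05)
})

test_that("labelling is equivariant under cyclic axis permutation", {
  g <- geometry_params()
  set.seed(7)
  n <- 2e4
  pts <- matrix(runif(3 * n, 0, g$x_r), ncol = 3)
  lab <- as.character(classify_point(pts[, 1], pts[, 2], pts[, 3], g))
  # sigma(x,y,z) = (z,x,y) maps each capillary onto another
  lab_perm <- as.character(classify_point(pts[, 3], pts[, 1], pts[, 2], g))
  map <- c(ECF = "ECF", BBB = "BBB", PL_IN = "PL_IN", PL_OUT = "PL_OUT",
           PL_X1 = "PL_Y1", PL_X2 = "PL_Y3", PL_X3 = "PL_Y2", PL_X4 = "PL_Y4",
           PL_Y1 = "PL_Z1", PL_Y2 = "PL_Z2", PL_Y3 = "PL_Z3", PL_Y4 = "PL_Z4",
           PL_Z1 = "PL_X1", PL_Z2 = "PL_X3", PL_Z3 = "PL_X2", PL_Z4 = "PL_X4")
  expect_equal(unname(map[lab]), lab_perm)
})

test_that("build_mesh resolves the capillaries and reports exact areas", {
  g <- geometry_params()
  m <- build_mesh(g, 18)
  expect_equal(m$nc, 17)
  # labels agree with classify_point at cell centres
  relab <- classify_point(m$coords[, 1], m$coords[, 2], m$coords[, 3], g)
  expect_equal(as.character(m$label), as.character(relab))
  # interface faces connect exactly one plasma and one ECF cell
  expect_true(all(m$plasma[m$faces$plasma]))
  expect_true(all(!m$plasma[m$faces$ecf]))
  # one rib side sums to the tabulated BBB area per capillary side
  x1 <- which(m$label == "PL_X1")
  f_x1_z <- m$faces[m$faces$plasma %in% x1 & m$faces$axis == 3, ]
  expect_equal(sum(f_x1_z$area), g$d_cap * g$r, tolerance = 1e-12)
  expect_equal(m$side_area_m2, 1.25e-10, tolerance = 1e-12)
  # total volume splits exactly between plasma and ECF
  expect_equal(m$V_ecf_m3 + m$V_pl_m3, g$x_r^3, tolerance = 1e-12)
  expect_error(build_mesh(g, 5), class = "bu_resolution_error")
  expect_match(tryCatch(build_mesh(g, 4), error = conditionMessage), "minimum n is 6")
})

test_that("ECF volume matches a Monte-Carlo classification oracle within 1%", {
  g <- geometry_params()
  m <- build_mesh(g, 18)
  set.seed(123)
  n <- 1e6
  pts <- matrix(runif(3 * n, 0, g$x_r), ncol = 3)
  lab <- classify_point(pts[, 1], pts[, 2], pts[, 3], g)
  frac_mc <- mean(lab == "ECF")
  frac_mesh <- m$V_ecf_m3 / g$x_r^3
  expect_lt(abs(frac_mesh - frac_mc) / frac_mc, 0.01)
})

test_that("mesh labels are deterministic and preserved under refinement", {
  g <- geometry_params()
  m1 <- build_mesh(g, 18)
  m2 <- build_mesh(g, 18)
  expect_identical(as.character(m1$label), as.character(m2$label))
  expect_identical(m1$faces, m2$faces)
  # labels are a pure function of coordinates: any refined mesh agrees with
  # the coarse labels at coincident cell centres
  m3 <- build_mesh(g, 33)  # interior cells nest 15 -> 30
  shared <- which(m3$coords[, 1] %in% m1$coords[, 1] &
                  m3$coords[, 2] %in% m1$coords[, 2] &
                  m3$coords[, 3] %in% m1$coords[, 3])
  key <- function(co) paste(signif(co[, 1], 12), signif(co[, 2], 12), signif(co[, 3], 12))
  k1 <- key(m1$coords)
  k3 <- key(m3$coords[shared, , drop = FALSE])
  hit <- match(k3, k1)
  expect_gt(sum(!is.na(hit)), 0)
  expect_equal(as.character(m3$label[shared[!is.na(hit)]]),
               as.character(m1$label[hit[!is.na(hit)]]))
})

test_that("the capillary network is one connected path system from inlet to outlet", {
  g <- geometry_params()
  m <- build_mesh(g, 18)
  pl <- which(m$plasma)
  dyn <- setdiff(pl, c(m$in_id, m$out_id))
  edges <- list()
  for (p in dyn) {
    q <- m$upwind[p]
    if (!is.na(q)) edges[[length(edges) + 1L]] <- c(q, p)
    else for (f in m$feeders[[p]]) edges[[length(edges) + 1L]] <- c(f, p)
  }
  for (f in m$feeders[[m$out_id]]) edges[[length(edges) + 1L]] <- c(f, m$out_id)
  E <- do.call(rbind, edges)
  reach <- m$in_id
  repeat {
    new <- setdiff(unique(E[E[, 1] %in% reach, 2]), reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  expect_setequal(reach, pl)
  # flow direction matches the capillary label on every rib cell
  labs <- as.character(m$label)
  expect_true(all(m$flow_axis[grepl("PL_X", labs)] == 1))
  expect_true(all(m$flow_axis[grepl("PL_Y", labs)] == 2))
  expect_true(all(m$flow_axis[grepl("PL_Z", labs)] == 3))
})

test_that("mesh CSV export round-trips the cell table", {
  g <- geometry_params()
  m <- build_mesh(g, 8)
  path <- tempfile(fileext = ".csv")
  write_mesh_csv(m, path)
  df <- read.csv(path)
  expect_equal(nrow(df), m$ncell)
  expect_equal(df$label, as.character(m$label))
  expect_equal(df$x, m$coords[, 1], tolerance = 1e-12)
  unlink(path)
})
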