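test_that("the unthinned optical-property grid has 1000 x 30 = 30000 nodes", {
  g <- grid_spec(mu_a_thin = 1, mu_sp_thin = 1)
  expect_length(g$mu_a, 1000)
  expect_length(g$mu_sp, 30)
  expect_equal(length(g$mu_a) * length(g$mu_sp), 30000)
  # thinned desk-scale default
  gd <- grid_spec()
  expect_equal(length(gd$mu_a) * length(gd$mu_sp), 3000)
})

test_that("database reflectance strictly decreases along mu_a at fixed mu_s'", {
  db <- tiny_db()
  for (s in unique(db$mu_sp)) {
    rows <- db[db$mu_sp == s, ]
    expect_true(all(diff(rows$R1) < 0))
    expect_true(all(diff(rows$R2) < 0))
  }
})

test_that("bilinear forward interpolation is exact at nodes and linear between", {
  db <- tiny_db()
  prov <- attr(db, "provenance")
  i <- 3; j <- 2
  node <- db[db$mu_a == prov$mu_a_nodes[i] & db$mu_sp == prov$mu_sp_nodes[j], ]
  R <- forward_interpolate(db, node$mu_a, node$mu_sp)
  expect_equal(unname(R[1, ]), c(node$R1, node$R2), tolerance = 1e-12)

  a_mid <- (prov$mu_a_nodes[i] + prov$mu_a_nodes[i + 1]) / 2
  nxt <- db[db$mu_a == prov$mu_a_nodes[i + 1] & db$mu_sp == prov$mu_sp_nodes[j], ]
  Rm <- forward_interpolate(db, a_mid, node$mu_sp)
  expect_equal(unname(Rm[1, 1]), (node$R1 + nxt$R1) / 2, tolerance = 1e-12)
  expect_equal(unname(Rm[1, 2]), (node$R2 + nxt$R2) / 2, tolerance = 1e-12)

  expect_error(forward_interpolate(db, 2, 1), "outside")
  expect_error(forward_interpolate(db, 0.1, 5), "outside")
})

test_that("training rejects degenerate databases", {
  db <- tiny_db()
  small <- db[1:2, ]
  attr(small, "provenance") <- attr(db, "provenance")
  class(small) <- class(db)
  expect_error(train_inverse_model(small), "insufficient data")
})

test_that("training is deterministic for a fixed seed", {
  db <- tiny_db()
  m1 <- train_inverse_model(db, hidden = c(8, 8), seed = 3, chunks = 10,
                            iter_per_chunk = 40, patience = 3, n_restarts = 1)
  m2 <- train_inverse_model(db, hidden = c(8, 8), seed = 3, chunks = 10,
                            iter_per_chunk = 40, patience = 3, n_restarts = 1)
  expect_identical(m1$validation_loss, m2$validation_loss)
  expect_identical(m1$theta, m2$theta)
})

test_that("round-trip inversion recovers coarse-grid optical properties", {
  db <- tiny_db()
  m <- tiny_model()
  set.seed(21)
  iv <- sample(nrow(db), 60)
  rec <- invert_reflectance(m, db$R1[iv], db$R2[iv])
  ea <- abs(rec$mu_a - db$mu_a[iv]) / db$mu_a[iv]
  es <- abs(rec$mu_sp - db$mu_sp[iv]) / db$mu_sp[iv]
  expect_lt(median(ea, na.rm = TRUE), 0.15)
  expect_lt(median(es, na.rm = TRUE), 0.15)
})

test_that("recovered mu_a is monotone along a coarse true-mu_a sweep", {
  db <- tiny_db()
  m <- tiny_model()
  prov <- attr(db, "provenance")
  s <- prov$mu_sp_nodes[4]
  rows <- db[db$mu_sp == s, ]
  idx <- round(seq(2, nrow(rows) - 1, length.out = 5))
  rec <- invert_reflectance(m, rows$R1[idx], rows$R2[idx])
  expect_true(all(diff(rec$mu_a) > 0))
})

test_that("inversion flags nonpositive and out-of-domain reflectance", {
  m <- tiny_model()
  db <- tiny_db()
  mid <- db[round(nrow(db) / 2), ]  # a genuine in-domain pair
  rec <- invert_reflectance(m, c(mid$R1, -1, 0, 1e5), c(mid$R2, 1e-5, 1e-5, 1e5))
  expect_false(rec$out_of_domain[1])
  expect_true(all(rec$out_of_domain[2:4]))
  expect_true(all(is.na(rec$mu_a[2:4])))
  expect_false(is.na(rec$mu_a[1]))
})

test_that("model serialization round-trips bit-stably for predictions", {
  m <- tiny_model()
  path <- tempfile(fileext = ".json")
  write_inverse_model(m, path)
  m2 <- read_inverse_model(path)
  db <- tiny_db()
  probe_rows <- db[seq(1, nrow(db), length.out = 25), ]
  r1 <- invert_reflectance(m, probe_rows$R1, probe_rows$R2)
  r2 <- invert_reflectance(m2, probe_rows$R1, probe_rows$R2)
  expect_lt(max(abs(r1$mu_a - r2$mu_a), abs(r1$mu_sp - r2$mu_sp)), 1e-10)
  unlink(path)
})

test_that("database text serialization round-trips and checks geometry", {
  db <- tiny_db()
  path <- tempfile(fileext = ".tsv")
  write_reflectance_database(db, path)
  db2 <- read_reflectance_database(path, expect_probe = test_probe())
  expect_equal(db2$R1, db$R1, tolerance = 1e-14)
  expect_equal(attr(db2, "provenance")$geometry_hash,
               geometry_hash(test_probe()))
  other <- probe_geometry(sds_list = c(1.5, 2.5))
  expect_error(read_reflectance_database(path, expect_probe = other),
               "geometry hash mismatch")
  unlink(path)
})
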