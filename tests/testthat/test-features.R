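test_that("parcel means match direct arithmetic on tiny volumes", {
  atlas <- parcel_atlas(array(c(1L, 1L, 2L), dim = c(3, 1, 1)))
  vol <- array(c(1, 3, 5), dim = c(3, 1, 1))
  expect_equal(parcel_reduce(vol, atlas), c("1" = 2, "2" = 5))
  const <- array(7, dim = c(3, 1, 1))
  expect_equal(unname(parcel_reduce(const, atlas)), c(7, 7))
})

test_that("parcel means equal a brute-force grouped-mean oracle", {
  set.seed(21)
  dims <- c(6, 5, 4)
  labels <- array(sample(0:9, prod(dims), replace = TRUE), dim = dims)
  vol <- array(rnorm(prod(dims)), dim = dims)
  atlas <- parcel_atlas(labels)
  got <- parcel_reduce(vol, atlas)
  for (id in atlas$parcel_ids) {
    acc <- 0; cnt <- 0
    for (i in seq_along(labels)) {
      if (labels[i] == id) { acc <- acc + vol[i]; cnt <- cnt + 1 }
    }
    expect_equal(unname(got[as.character(id)]), acc / cnt)
  }
})

test_that("parcel reduction is linear and voxel-order invariant", {
  set.seed(22)
  labels <- array(sample(1:4, 60, replace = TRUE), dim = c(60, 1, 1))
  atlas <- parcel_atlas(labels)
  v <- array(rnorm(60), dim = c(60, 1, 1))
  w <- array(rnorm(60), dim = c(60, 1, 1))
  lhs <- parcel_reduce(2 * v + 3 * w, atlas)
  rhs <- 2 * parcel_reduce(v, atlas) + 3 * parcel_reduce(w, atlas)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  perm <- sample(60)
  atlas_p <- parcel_atlas(array(labels[perm], dim = dim(labels)))
  expect_equal(parcel_reduce(array(v[perm], dim = dim(v)), atlas_p),
               parcel_reduce(v, atlas), tolerance = 1e-12)
})

test_that("shape mismatches and empty parcels are loud errors", {
  atlas <- parcel_atlas(array(1:2, dim = c(2, 1, 1)), parcel_ids = 1:3)
  expect_error(parcel_reduce(array(0, dim = c(3, 1, 1)), atlas), "shape")
  vol <- array(c(1, 2), dim = c(2, 1, 1))
  expect_error(parcel_reduce(vol, atlas), "no voxels")
  means <- parcel_reduce(vol, atlas, allow_missing = TRUE)
  expect_true(is.na(means["3"]))
  expect_equal(unname(means[c("1", "2")]), c(1, 2))
})

test_that("assembled matrices have the design shape and fixed encoding", {
  ns <- 25
  vecs <- list()
  subject <- integer(); condition <- character()
  k <- 0
  for (s in seq_len(ns)) {
    for (cond in dual_task_conditions) {
      k <- k + 1
      vecs[[k]] <- setNames(rnorm(5), c(2, 5, 9, 11, 17))
      subject[k] <- s; condition[k] <- cond
    }
  }
  fm <- assemble_matrix(vecs, subject, condition)
  expect_equal(dim(fm), c(100L, 5L))
  expect_equal(fm$parcel_ids, c(2L, 5L, 9L, 11L, 17L))
  expect_equal(sort(unique(fm$labels)), 0:3)
  expect_equal(fm$labels[fm$condition == "SpH_VisH"],
               rep(3L, 25))
  # rows ordered by subject then condition code
  expect_equal(fm$subject, rep(seq_len(ns), each = 4))
})

test_that("duplicate rows and inconsistent parcel sets are rejected", {
  v <- setNames(rnorm(3), 1:3)
  expect_error(
    assemble_matrix(list(v, v), c(1, 1), c("SpE_VisE", "SpE_VisE")),
    "duplicate|equal across classes")
  w <- setNames(rnorm(3), c(1, 2, 4))
  expect_error(
    assemble_matrix(list(v, w), c(1, 1), c("SpE_VisE", "SpE_VisH")),
    "inconsistent")
})

test_that("feature matrices round-trip through TSV", {
  fm <- small_fm(seed = 23, n_subjects = 4, n_parcels = 15)
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$parcel_ids, fm$parcel_ids)
  unlink(path)
})

test_that("volumes and atlases round-trip through NIfTI", {
  dims <- c(8, 7, 6)
  set.seed(24)
  labels <- array(sample(0:5, prod(dims), replace = TRUE), dim = dims)
  vol <- array(rnorm(prod(dims)), dim = dims)
  fl <- tempfile(fileext = ".nii.gz")
  fv <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(labels, fl)
  RNifti::writeNifti(vol, fv)
  atlas <- parcel_atlas(array(as.integer(round(RNifti::readNifti(fl))),
                              dim = dims))
  got <- parcel_reduce(array(as.numeric(RNifti::readNifti(fv)), dim = dims),
                       atlas)
  expect_equal(got, parcel_reduce(vol, parcel_atlas(labels)),
               tolerance = 1e-6)
  unlink(c(fl, fv))
})
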