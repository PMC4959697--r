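# Domain types and file I/O: tabular, coordinate and NIFTI readers, pair
# normalization, report and BrainNet export.

test_that("coordinate background: line number becomes the id", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 20 30", "-5 0 5", "1 2 3"), f)
  sp <- read_background(f, "coords")
  expect_equal(sp$M, 3L)
  expect_equal(sp$ids, 1:3)
  expect_equal(sp$coords[2, ], c(-5, 0, 5), ignore_attr = TRUE)
})

test_that("duplicate coordinate lines are distinct positions with a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "1 2 3"), f)
  expect_warning(sp <- read_background(f, "coords"), "distinct")
  expect_equal(sp$M, 2L)
})

test_that("tabular groups read and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("5 1", "9 1", "12 2"), f)
  sp <- position_space(1:20)
  g <- read_position_groups(f, sp)
  expect_equal(g$groups, list(`1` = c(5L, 9L), `2` = 12L))
  # round trip: write what we read, read it again
  f2 <- withr::local_tempfile(fileext = ".txt")
  rows <- do.call(rbind, lapply(names(g$groups), function(k)
    cbind(g$groups[[k]], as.integer(k))))
  write.table(rows, f2, row.names = FALSE, col.names = FALSE)
  expect_equal(read_position_groups(f2, sp)$groups, g$groups)
})

test_that("group files with ids outside the background are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("5 1", "99 1"), f)
  expect_error(read_position_groups(f, position_space(1:20)), "absent")
})

test_that("empty group file errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_error(read_position_groups(f, position_space(1:20)), "no groups")
})

test_that("pair normalization is orientation-invariant and flags issues", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 7 1", "7 3 1", "2 9 1"), f)
  sp <- position_space(1:10)
  expect_warning(cg <- read_connection_groups(f, sp), "duplicate")
  expect_equal(edge_key_set(cg$groups[["1"]]), c("2 9", "3 7"))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("7 3 1", "9 2 1"), f2)
  cg2 <- read_connection_groups(f2, sp)
  expect_equal(edge_key_set(cg2$groups[["1"]]),
               edge_key_set(cg$groups[["1"]]))

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("4 4 1", f3)
  expect_error(read_connection_groups(f3, sp), "elf-connection")
})

test_that("annotation reads names, applies legends, restricts to background", {
  sp <- position_space(1:10)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 VN", "2 VN", "3 AN"), f)
  ann <- read_annotation(f, sp)
  expect_equal(ann$classes, list(AN = 3L, VN = c(1L, 2L)))

  # integer codes + legend
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 1", "2 1", "3 2"), f2)
  lg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 VN", "2 AN"), lg)
  expect_equal(read_annotation(f2, sp, legend = lg)$classes, ann$classes)
  lg2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 VN", lg2)
  expect_error(read_annotation(f2, sp, legend = lg2), "legend label missing")

  # ids outside the background are dropped, K = |B intersect S|
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 VN", "2 VN", "77 VN", "88 AN"), f3)
  expect_message(ann3 <- read_annotation(f3, sp), "dropped")
  expect_equal(lengths(ann3$classes), c(VN = 2L))
})

test_that("NIFTI volumes round-trip and group labels are counted correctly", {
  dims <- c(3L, 3L, 3L)
  vol <- array(0L, dims)
  vol[c(1, 5)] <- 1L                 # two voxels in group 1
  vol[c(10, 14, 27)] <- 2L           # three voxels in group 2
  mask <- array(1L, dims)
  aff <- rbind(c(2, 0, 0, -2), c(0, 2, 0, -2), c(0, 0, 2, -2), c(0, 0, 0, 1))
  d <- withr::local_tempdir()
  write_nifti(mask, file.path(d, "mask.nii"), aff)
  write_nifti(vol, file.path(d, "groups.nii.gz"), aff)

  sp <- read_background(file.path(d, "mask.nii"), "nifti")
  expect_equal(sp$M, 27L)
  expect_equal(sp$coords[1, ], c(-2, -2, -2), ignore_attr = TRUE)

  g <- read_position_groups(file.path(d, "groups.nii.gz"), sp, "nifti")
  expect_equal(lengths(g$groups), c(`1` = 2L, `2` = 3L))
  expect_equal(g$groups[["2"]], c(10L, 14L, 27L))

  img <- read_nifti(file.path(d, "groups.nii.gz"))
  expect_identical(as.integer(img$data), as.integer(vol))
  expect_equal(img$affine, aff)
})

test_that("non-integer NIFTI group labels are rejected", {
  d <- withr::local_tempdir()
  vol <- array(0, c(2, 2, 2)); vol[1] <- 1.5
  write_nifti(vol, file.path(d, "bad.nii"))
  sp <- position_space(1:8)
  expect_error(read_position_groups(file.path(d, "bad.nii"), sp, "nifti"),
               "non-integer")
})

test_that("report is sorted by q, filterable, and header-only when empty", {
  study <- toy_position_study()
  res <- suppressMessages(
    run_position_analysis(study$groups, study$annotation, study$space))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(res))
  expect_equal(names(tab), names(res))
  expect_false(is.unsorted(tab$q))
  write_report(res, f, alpha = 0.05)
  expect_equal(nrow(read.delim(f)), sum(res$q <= 0.05))
  write_report(res[0, ], f)
  expect_equal(nrow(read.delim(f)), 0L)
})

test_that("BrainNet export writes node files for overlaps, edge matrices for connections", {
  study <- toy_position_study()
  res <- suppressMessages(
    run_position_analysis(study$groups, study$annotation, study$space))
  d <- withr::local_tempdir()
  # force one known significant row
  res$q <- 1; res$q[res$group == "roiA" & res$class == "VN"] <- 0.01
  files <- export_brainnet(res, study$space, study$groups, study$annotation,
                           file.path(d, "bn"))
  expect_length(files, 1L)
  node <- read.delim(files[1L], header = FALSE)
  expect_equal(nrow(node), 4L)            # |roiA intersect VN| = |1:4| = 4

  # connection case: 3 edges among 4 nodes -> symmetric 0/1 matrix, 6 ones
  sp <- position_space(1:6, coords = cbind(1:6, 0, 0))
  cg <- connection_groups(list(g1 = rbind(c(1, 3), c(1, 4), c(2, 3))))
  ann <- neuro_annotation(list(C = 1:2, D = 3:4))
  cres <- suppressMessages(
    run_connection_analysis(cg, ann, sp, tests = "HG"))
  cres$q <- ifelse(cres$class == "C-D", 0.001, 1)
  cfiles <- export_brainnet(cres, sp, cg, ann, file.path(d, "cn"))
  edge <- as.matrix(read.delim(grep("\\.edge$", cfiles, value = TRUE),
                               header = FALSE))
  expect_equal(dim(edge), c(4L, 4L))
  expect_equal(sum(edge), 6)
  expect_true(all(edge == t(edge)))

  # nothing significant -> no files, message
  res$q <- 1
  expect_message(
    none <- export_brainnet(res, study$space, study$groups,
                            study$annotation, file.path(d, "empty")),
    "nothing exported")
  expect_length(none, 0L)

  # missing coordinates -> error
  expect_error(
    export_brainnet(cres, position_space(1:6), cg, ann, file.path(d, "x")),
    "coordinates")
})
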