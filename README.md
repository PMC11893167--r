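# ribomesh

Membrane-contextual morphometrics of mitochondria-associated cytoplasmic
ribosomes from cryo-electron tomography geometry.

Most mitochondrial proteins are made by cytoplasmic ribosomes and imported
through the outer mitochondrial membrane (OMM). In cryo-ET of cells,
subtomogram averaging yields each ribosome's position and ZYZ Euler
orientation, and membrane segmentation yields triangulated OMM/IMM surface
meshes. `ribomesh` turns those two inputs into quantitative membrane
context, for structural cell biologists analysing particle tables + surface
meshes:

1. **Classify** — for each ribosome, the distance to the nearest OMM
   triangle, three relative angles `arccos(|R·u · n̂|)` between its rotated
   body axes and the local membrane normal, and the position of its peptide
   exit tunnel; ribosomes whose exit tunnel lies within 95 Å of the OMM are
   *import-oriented*, others within 250 Å of the membrane are
   *proximal non-import*.
2. **Cluster** — Ripley's K, `K(r) = V/(n(n−1)) Σ 1(d_ij ≤ r)`, over
   r = 27–166 nm against a surface-constrained complete-spatial-randomness
   null (area-weighted resampling on the same membrane), summarised as the
   maximum `K(r)/K_CSR(r)` per 10-nm interval and compared across classes
   with a Mann–Whitney U test.
3. **Patches** — OMM triangles within 150 Å of the triangles nearest to
   import-oriented ribosomes (co-translation-associated patches), a count-
   and spacing-matched randomized null, crista-associated OMM from the
   18–30 nm crista-junction distance band expanded by 15 nm, and the
   overlap fraction `area(ribo ∩ crista)/area(ribo)`.
4. **Distances** — per-triangle OMM–IMM distance fields (nearest-point and
   normal-cone methods), 100-bin histograms per patch class, and their
   peaks.
5. **Polysomes** — chains of import-oriented ribosomes whose 3′ mRNA entry
   sites sit directly adjacent to a ≤ 30 nm neighbour's 5′ mRNA exit site,
   with 5′→3′ end-to-end and path lengths.

A synthetic scene generator (`make_mitochondrion()`,
`decorate_particles()`) builds nested OMM/IMM icosphere meshes with
controllable spacing fields, crista-junction wells, planted orientation
classes, clustering and polysome chains — so every stage is testable with
known ground truth and no tomography data. I/O covers star-dialect particle
tables (pixel→Å at ingest), STL meshes with a per-triangle CSV attribute
sidecar, per-tomogram context-record CSVs, and a JSON run configuration.

## Worked example

```r
library(ribomesh)

scene <- make_mitochondrion(radius = 3000, spacing = 135, n_cj_wells = 3, seed = 1)
deco  <- decorate_particles(scene$omm, n = 200, import_fraction = 0.4, seed = 2)

rec <- compute_context(deco$particles, scene$omm)
summarize_classes(rec)$pooled
#>   n_import n_proximal_non_import n_background import_fraction import_percent
#> 1      116                    84            0            0.58             58
```

200 ribosomes sit 135 Å above a 3000 Å OMM sphere; 40% were planted with
the exit tunnel toward the membrane and all of those classify as
import-oriented, while a geometric chance fraction (~1/3) of the randomly
oriented rest also passes the 95 Å rule — hence 58% rather than 40%.

```r
imp <- rec$orientation_class == "import_oriented"
kc  <- k_curve(as.matrix(deco$particles[imp, c("x", "y", "z")]), scene$omm,
               run_config(), n_resamples = 50, standoff = 135, seed = 3)
im <- interval_maxima(kc, 10)
im[im$lo == 30, ]
#>   lo hi max_ratio
#> 2 30 40  1.139241
```

The (30, 40] nm interval maximum of `K/K_CSR` is ~1.14: these particles
were placed without clustering, so the ratio hovers near 1 (clustered
decorations score well above it).

```r
crista  <- crista_associated_omm(scene$omm, scene$imm)
patches <- build_patches(rec$nearest_triangle_id[imp], scene$omm, radius = 150)
overlap_fraction(patches, crista)
#> [1] 0.03255062

chains <- decorate_particles(scene$omm, 12, mode = "chains",
                             chain_lengths = c(5L, 4L, 3L), seed = 4)
detect_chains(chains$particles)
#> <polysome_chains> 3 chain(s)
#>   #1: 5 members, end-to-end 1423 A, path 1435 A
#>   #2: 4 members, end-to-end 1133 A, path 1139 A
#>   #3: 3 members, end-to-end 840 A, path 843 A
```

Uniformly placed ribosome patches overlap the three crista-junction wells
only ~3% by area; the three planted polysome chains are recovered exactly,
with a 5-mer spanning 1423 Å end to end (4 × 300 Å spacing plus the
terminal mRNA site offsets, slightly shortened by membrane curvature).

`run_pipeline(config, out_dir)` (or the thin wrapper in
`inst/scripts/ribomesh-pipeline.R`) chains all stages over many simulated
tomograms and writes per-tomogram CSVs, study-level tables, and a
`summary.json`; reruns with the same seed are byte-identical.

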