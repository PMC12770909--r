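# File formats

All exchange formats are plain text. Node indices on disk are 0-based;
in-memory R objects are 1-based.

## Meshes (`read_mesh()` / `write_mesh()`)

* **Gmsh MSH v2.2 ASCII** (`.msh`): `$Nodes` block of `id x y z` (ids may
  be non-consecutive; remapped on read), `$Elements` block where only
  element type 2 (3-node triangle) is consumed; any tag count is accepted.
  Coordinates in mm.
* **ASCII PLY** (`.ply`): `element vertex` with `x y z` as the first three
  properties, `element face` with `property list uchar int
  vertex_indices` (0-based, converted on read).

Both writers emit coordinates with `%.17g`, so a write/read round trip is
bit-exact.

## Basis fields (`read_fields_tsv()` / `write_fields_tsv()`)

Tab-separated, one row per node:

| column | meaning |
|---|---|
| `node_index` | 0-based node index |
| `er1_x er1_y er1_z` | basis field of the return-vs-surround-1 solve (V/m per mA) |
| `ec1_x ec1_y ec1_z` | basis field of the return-vs-central-1 solve |
| `er2_x er2_y er2_z` | basis field of the return-vs-surround-2 solve |

preceded by `#!` metadata lines: `io` (mA), `f` (Hz), `montage_id`,
`individual_id`. Values written with `%.17g` (bit-exact round trip).

## Region labels (`read_labels_tsv()` / `write_labels_tsv()`)

Tab-separated with header `node_index	label`: 0-based node index, integer
region label. Region sets (which labels form `M1_left`, `M1_right`,
`surrounding`) are supplied separately (`region_labels` in the pipeline
configuration).

## Threshold masks (`mask_table()`)

`node_index` (0-based), `status` ∈ `kept` / `excluded` / `zeroed`.

## Pipeline outputs (`run_pipeline()`)

* `metrics.tsv` — long table: `individual_id`, `montage_id`, `phase_lag`
  (rad), `region_set` (`M1s`, `surrounding`, `M1_left`, `M1_right`),
  `metric` (`peak_magnitude`, `peak_normal`, `rdm`, `dotp`, `delta_dotp`,
  `effective_area`), `value`, `units`.
* `tests.tsv` — `metric`, `montage_id`, `region_set`, `statistic`,
  `p_raw`, `p_adjusted` (Holm across montages within metric × region),
  `n_permutations`, `seed`.
* `cv.tsv` — `metric`, `montage_id`, `region_set`, `cv` (percent).
* `selection_<objective>.tsv` — `individual_id`, `montage_id`.
* `individualization.json` — per objective: fixed-best montage, means and
  CVs for the fixed-best and individualized strategies.
* `manifest.json` — package and R versions, seed, configuration hash,
  table dimensions.
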