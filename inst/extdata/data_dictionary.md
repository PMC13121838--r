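# dirt file formats

All files are UTF-8 CSV, comma-separated, `.` decimal, with a header
row. Day indices are integers per person starting at 1; lapses are
supplied in the design table, never inferred from calendar dates.

## `<stem>_responses.csv` — one row per item administration

| column | type | meaning |
|--------|------|---------|
| person | int  | person index, 1..n_persons |
| day    | int  | test-date index within person |
| test   | int  | test index within the day |
| item   | int  | item index within the test |
| y      | 0/1  | correctness of the response |
| d      | num  | target (ensemble mean) difficulty of the test; constant within (person, day, test) |

## `<stem>_times.csv` — one row per test (absent in DIR mode)

| column  | type | meaning |
|---------|------|---------|
| person  | int  | person index |
| day     | int  | test-date index |
| test    | int  | test index within the day |
| seconds | num  | total response time for the test, > 0 (modelled on the log scale) |

## `<stem>_design.csv` — one row per person-day

| column    | type | meaning |
|-----------|------|---------|
| person    | int  | person index |
| day       | int  | test-date index |
| lapse     | num  | days since the previous test date (empty on each person's first day) |
| subpop    | int  | subpopulation id of the person |
| sigma_b   | num  | known sd of item difficulties around the target (repeated) |
| theta_M   | num  | maturity ceiling of the growth model (repeated) |
| h_max     | num  | lapse cap in days (repeated) |
| subpop_mu | num  | initial-ability prior mean of the person's subpopulation |
| subpop_sd | num  | initial-ability prior sd of the person's subpopulation |

## `<stem>_truth.json` — generating values of a simulation

Scalar or per-person arrays for `theta0`, `beta`, `gamma`, `lam_delta`,
`lam_e`, `lam_tau`, plus `rho`, `lam_theta`, `lam_eps`, `d_offset`, the
linkage `kind` and the `seed`.

## `<stem>_<group>.csv` — posterior draws, long format

| column    | type | meaning |
|-----------|------|---------|
| iteration | int  | retained-draw index (post burn-in, post thinning) |
| index     | int  | person index (`beta`, `gamma`, precision groups), person-date cell index in (person, day) order (`theta`), or 1 for shared scalars |
| value     | num  | the draw |

## `<stem>_manifest.json` — run manifest

`seed`, full configuration echo, md5 digests of the input files, package
version, timestamp; sufficient to reproduce a run bit-for-bit with the
same binaries.
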