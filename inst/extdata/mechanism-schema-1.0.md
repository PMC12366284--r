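# Mechanism JSON exchange format, version 1.0

A mechanism document is a single JSON object:

```json
{
  "format_version": "1.0",
  "mechanism": {
    "mechanism_id": "alpha-amylase",
    "annotations": {"ec": "3.2.1.1", "cath": "3.20.20.80"},
    "steps": [
      {
        "step_index": 1,
        "atoms": [
          {"atom_id": 1, "element": 6, "charge": 0}
        ],
        "bonds": [
          {"atoms": [1, 2], "order": "single"}
        ],
        "arrows": [
          {
            "electrons": 2,
            "source": {"type": "atom", "atoms": [13]},
            "sink": {"type": "incipient", "atoms": [13, 1]}
          }
        ]
      }
    ]
  }
}
```

Rules:

- `mechanism_id`: non-empty string, unique within a corpus.
- `annotations`: optional; free-form, preserved verbatim. Recognised
  entries: `ec` (EC number(s)), `cath` (CATH superfamily id(s) of the
  catalytic domains, `;`- or `,`-separated when several).
- `steps`: non-empty array; `step_index` values must be 1..n consecutive.
- `atoms`: `atom_id` integer, unique within the step; `element` atomic
  number 1–118; `charge` integer formal charge (omitted means 0).
  Hydrogens are explicit wherever they participate in the chemistry;
  readers perform no implicit-hydrogen expansion.
- `bonds`: unordered atom pairs, both present in the step, no self-bonds,
  at most one bond per pair; `order` one of `single`, `double`, `triple`,
  `aromatic` (aromatic is never kekulized).
- `arrows`: non-empty array. `electrons` is 1 or 2. `source.type` is
  `atom` (lone pair / radical; one atom id) or `bond` (an existing bond;
  its two atom ids). `sink.type` is `atom`, `bond` (existing), or
  `incipient` (ordered pair of atom ids for a bond being formed). Source
  and sink must differ; all references must resolve within the step.

Writers emit atoms sorted by `atom_id`, bonds sorted by their (low, high)
atom pair, keys in the order shown above, and two-space indentation, so a
given mechanism always serializes to identical bytes.
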