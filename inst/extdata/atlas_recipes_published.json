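{
  "dialect": "as-published",
  "comment": "Named series/parallel reduction chains for the carotid tree, transcribed as published. The resistance and compliance chains share their topology but differ in the LOFA (B10) multiplicity of step 1 (16 copies in R1, 1 copy in C1) and both use 15 effective MOFA (B22) copies in step 9 although the stated factor is 16; these inconsistencies are surfaced by the discrepancy report, not silently repaired. Step 19 states no combination mode; parallel is used (MCA and ACA are parallel daughter branches) and the step is flagged because neither mode reproduces the published value.",
  "resistance": [
    {"name": "R1",  "mode": "parallel", "children": [{"ref": "B8", "factor": 1}, {"ref": "B9", "factor": 1}, {"ref": "B10", "factor": 16}]},
    {"name": "R2",  "mode": "series",   "children": [{"ref": "R1"}, {"ref": "B7"}]},
    {"name": "R3",  "mode": "series",   "children": [{"ref": "R2"}, {"ref": "B6"}, {"ref": "B4"}]},
    {"name": "R4",  "mode": "parallel", "children": [{"ref": "R3", "factor": 2}, {"ref": "B5", "factor": 1}]},
    {"name": "R5",  "mode": "parallel", "children": [{"ref": "B3", "factor": 9}]},
    {"name": "R6",  "mode": "parallel", "children": [{"ref": "R5", "factor": 1}, {"ref": "B2", "factor": 1}]},
    {"name": "R7",  "mode": "series",   "children": [{"ref": "R4"}, {"ref": "R6"}]},
    {"name": "R8",  "mode": "series",   "children": [{"ref": "B16"}, {"ref": "B17"}, {"ref": "B18"}]},
    {"name": "R9",  "mode": "parallel", "children": [{"ref": "B22", "factor": 15, "stated_factor": 16}]},
    {"name": "R10", "mode": "parallel", "children": [{"ref": "R9", "factor": 1}, {"ref": "B23", "factor": 1}, {"ref": "B12", "factor": 1}]},
    {"name": "R11", "mode": "parallel", "children": [{"ref": "R10", "factor": 1}, {"ref": "B15", "factor": 1}]},
    {"name": "R12", "mode": "series",   "children": [{"ref": "R11"}, {"ref": "R8"}]},
    {"name": "R13", "mode": "parallel", "children": [{"ref": "R12", "factor": 2}]},
    {"name": "R14", "mode": "parallel", "children": [{"ref": "B24", "factor": 7.6}]},
    {"name": "R15", "mode": "parallel", "children": [{"ref": "R14", "factor": 1}, {"ref": "B25", "factor": 1}]},
    {"name": "R16", "mode": "parallel", "children": [{"ref": "R15", "factor": 1}, {"ref": "B19", "factor": 1}]},
    {"name": "R17", "mode": "parallel", "children": [{"ref": "R12", "factor": 1}, {"ref": "R16", "factor": 1}]},
    {"name": "R18", "mode": "series",   "children": [{"ref": "B14"}, {"ref": "R17"}]},
    {"name": "R19", "mode": "parallel", "children": [{"ref": "R7", "factor": 1}, {"ref": "R18", "factor": 1}]},
    {"name": "R20", "mode": "parallel", "children": [{"ref": "B36", "factor": 1}, {"ref": "B35", "factor": 1}]},
    {"name": "R21", "mode": "series",   "children": [{"ref": "R20"}, {"ref": "B38"}]},
    {"name": "R22", "mode": "parallel", "children": [{"ref": "R21", "factor": 1}, {"ref": "B34", "factor": 1}]},
    {"name": "R23", "mode": "series",   "children": [{"ref": "R22"}, {"ref": "B38"}]},
    {"name": "R24", "mode": "parallel", "children": [{"ref": "R23", "factor": 1}, {"ref": "B33", "factor": 1}]},
    {"name": "R25", "mode": "series",   "children": [{"ref": "R24"}, {"ref": "B37"}]},
    {"name": "R26", "mode": "parallel", "children": [{"ref": "B31", "factor": 1}, {"ref": "B32", "factor": 1}]},
    {"name": "R27", "mode": "parallel", "children": [{"ref": "R25", "factor": 1}, {"ref": "R26", "factor": 1}]},
    {"name": "R28", "mode": "series",   "children": [{"ref": "R27"}, {"ref": "B37"}]},
    {"name": "R29", "mode": "parallel", "children": [{"ref": "R28", "factor": 1}, {"ref": "B29", "factor": 1}, {"ref": "B30", "factor": 1}]}
  ],
  "compliance": [
    {"name": "C1",  "mode": "parallel", "children": [{"ref": "B8", "factor": 1}, {"ref": "B9", "factor": 1}, {"ref": "B10", "factor": 1}]},
    {"name": "C2",  "mode": "series",   "children": [{"ref": "C1"}, {"ref": "B7"}]},
    {"name": "C3",  "mode": "series",   "children": [{"ref": "C2"}, {"ref": "B6"}, {"ref": "B4"}]},
    {"name": "C4",  "mode": "parallel", "children": [{"ref": "C3", "factor": 2}, {"ref": "B5", "factor": 1}]},
    {"name": "C5",  "mode": "parallel", "children": [{"ref": "B3", "factor": 9}]},
    {"name": "C6",  "mode": "parallel", "children": [{"ref": "C5", "factor": 1}, {"ref": "B2", "factor": 1}]},
    {"name": "C7",  "mode": "series",   "children": [{"ref": "C4"}, {"ref": "C6"}]},
    {"name": "C8",  "mode": "series",   "children": [{"ref": "B16"}, {"ref": "B17"}, {"ref": "B18"}]},
    {"name": "C9",  "mode": "parallel", "children": [{"ref": "B22", "factor": 15, "stated_factor": 16}]},
    {"name": "C10", "mode": "parallel", "children": [{"ref": "C9", "factor": 1}, {"ref": "B23", "factor": 1}, {"ref": "B12", "factor": 1}]},
    {"name": "C11", "mode": "parallel", "children": [{"ref": "C10", "factor": 1}, {"ref": "B15", "factor": 1}]},
    {"name": "C12", "mode": "series",   "children": [{"ref": "C11"}, {"ref": "C8"}]},
    {"name": "C13", "mode": "parallel", "children": [{"ref": "C12", "factor": 2}]},
    {"name": "C14", "mode": "parallel", "children": [{"ref": "B24", "factor": 7.6}]},
    {"name": "C15", "mode": "parallel", "children": [{"ref": "C14", "factor": 1}, {"ref": "B25", "factor": 1}]},
    {"name": "C16", "mode": "parallel", "children": [{"ref": "C15", "factor": 1}, {"ref": "B19", "factor": 1}]},
    {"name": "C17", "mode": "parallel", "children": [{"ref": "C12", "factor": 1}, {"ref": "C16", "factor": 1}]},
    {"name": "C18", "mode": "series",   "children": [{"ref": "B14"}, {"ref": "C17"}]},
    {"name": "C19", "mode": "parallel", "children": [{"ref": "C7", "factor": 1}, {"ref": "C18", "factor": 1}]},
    {"name": "C20", "mode": "parallel", "children": [{"ref": "B36", "factor": 1}, {"ref": "B35", "factor": 1}]},
    {"name": "C21", "mode": "series",   "children": [{"ref": "C20"}, {"ref": "B38"}]},
    {"name": "C22", "mode": "parallel", "children": [{"ref": "C21", "factor": 1}, {"ref": "B34", "factor": 1}]},
    {"name": "C23", "mode": "series",   "children": [{"ref": "C22"}, {"ref": "B38"}]},
    {"name": "C24", "mode": "parallel", "children": [{"ref": "C23", "factor": 1}, {"ref": "B33", "factor": 1}]},
    {"name": "C25", "mode": "series",   "children": [{"ref": "C24"}, {"ref": "B37"}]},
    {"name": "C26", "mode": "parallel", "children": [{"ref": "B31", "factor": 1}, {"ref": "B32", "factor": 1}]},
    {"name": "C27", "mode": "parallel", "children": [{"ref": "C25", "factor": 1}, {"ref": "C26", "factor": 1}]},
    {"name": "C28", "mode": "series",   "children": [{"ref": "C27"}, {"ref": "B37"}]},
    {"name": "C29", "mode": "parallel", "children": [{"ref": "C28", "factor": 1}, {"ref": "B29", "factor": 1}, {"ref": "B30", "factor": 1}]}
  ]
}
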