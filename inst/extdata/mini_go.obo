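format-version: 1.2
ontology: go/subsets/mini
remark: synthetic three-level slice of the Gene Ontology used by the test suite and the simulator defaults

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0005575
name: cellular_component
namespace: cellular_component

[Term]
id: GO:0003824
name: catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0005488
name: binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0140110
name: transcription regulator activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0003700
name: DNA-binding transcription factor activity
namespace: molecular_function
is_a: GO:0140110 ! transcription regulator activity

[Term]
id: GO:0016301
name: kinase activity
namespace: molecular_function
is_a: GO:0003824 ! catalytic activity

[Term]
id: GO:0003677
name: DNA binding
namespace: molecular_function
is_a: GO:0005488 ! binding

[Term]
id: GO:0005215
name: transporter activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0065007
name: biological regulation
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0006355
name: regulation of DNA-templated transcription
namespace: biological_process
is_a: GO:0065007 ! biological regulation
relationship: part_of GO:0008152 ! metabolic process

[Term]
id: GO:0005622
name: intracellular anatomical structure
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0005634
name: nucleus
namespace: cellular_component
is_a: GO:0005622 ! intracellular anatomical structure

[Term]
id: GO:0000000
name: obsolete example term
is_obsolete: true
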