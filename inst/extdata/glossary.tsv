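space group	https://reference.example.org/space_group
plane group	https://reference.example.org/plane_group
group theory	https://reference.example.org/group
associative group	https://reference.example.org/group
inverse element	https://reference.example.org/group
unit cell	https://reference.example.org/unit_cell
asymmetric unit	https://reference.example.org/asymmetric_unit
structure factor	https://reference.example.org/structure_factor
displacement ellipsoid	https://reference.example.org/adp
hydrogen bond	https://reference.example.org/hydrogen_bond
torsion angle	https://reference.example.org/torsion_angle
#stop	group
#stop	cell
#stop	bond
#stop	angle
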