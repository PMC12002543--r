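ply
format ascii 1.0
comment unit cube, mm
element vertex 8
property double x
property double y
property double z
element face 12
property list uchar int vertex_indices
end_header
0 0 0
1 0 0
0 1 0
1 1 0
0 0 1
1 0 1
0 1 1
1 1 1
3 0 2 1
3 1 2 3
3 4 5 6
3 5 7 6
3 0 1 4
3 1 5 4
3 2 6 3
3 3 6 7
3 0 4 2
3 2 4 6
3 1 3 5
3 3 7 5
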