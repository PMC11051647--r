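# Example river-network specification for build_schematic_map() /
# read_network_spec(): axis-aligned waypoint polylines, (row, col) 1-based
# with row 1 at the North edge.  The tributary ends on a cell of the main
# river, declaring a confluence.
rivers:
- name: main
  waypoints:
  - [6, 2]
  - [6, 39]
- name: trib
  waypoints:
  - [2, 5]
  - [6, 5]
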