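# Bootstrap attribute dictionary: defines, in its own formalism, the
# attribute tags used to write CIF dictionaries.  The file validates
# against itself with zero violations.
data_on_this_dictionary
_dictionary_name  ddl_bootstrap.dic

data_dictionary_name
_name        '_dictionary_name'
_category    dictionary
_type        char
_list        no
_definition  'The file name or title of a dictionary.'

data_name
_name        '_name'
_category    dictionary_definition
_type        char
_list        both
_definition  'The tag defined by the enclosing data block.'

data_category
_name        '_category'
_category    dictionary_definition
_type        char
_list        no
_definition  'Identifier grouping related definitions.'

data_type
_name        '_type'
_category    dictionary_definition
_type        char
_list        no
loop_
 _enumeration
  numb
  char
_definition  'Data type of the defined tag: numeric or character.'

data_units
_name        '_units'
_category    dictionary_definition
_type        char
_list        no
_definition
;
 Preferred unit in which values of the defined tag are expressed.
 Declarative only: values are asserted to be in this unit and no
 conversion is ever performed.
;

data_enumeration
_name        '_enumeration'
_category    dictionary_definition
_type        char
_list        both
_definition  'An allowed value of the defined tag.'

data_enumeration_range
_name        '_enumeration_range'
_category    dictionary_definition
_type        char
_list        no
_definition
;
 Closed numeric range for the defined tag, written min:max with either
 bound optionally empty.  Requires _type numb.
;

data_list
_name        '_list'
_category    dictionary_definition
_type        char
_list        no
loop_
 _enumeration
  yes
  no
  both
_definition
;
 Whether the defined tag must appear in a loop (yes), must not (no),
 or may appear either way (both).
;

data_type_conditions
_name        '_type_conditions'
_category    dictionary_definition
_type        char
_list        no
loop_
 _enumeration
  su
_definition
;
 Additional type conditions; the value su permits a parenthesised
 trailing standard uncertainty on numeric values.
;

data_definition
_name        '_definition'
_category    dictionary_definition
_type        char
_list        no
_definition  'Human-readable prose defining the concept behind the tag.'
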