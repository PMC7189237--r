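# Default photosynthesis-related GO terms (anchored at GO:0015979).
# This is a curated list of widely used photosynthesis terms; substitute a
# study-specific list via select_negatives(photo_terms = ...) if needed.
GO:0015979 photosynthesis
GO:0019684 photosynthesis, light reaction
GO:0019685 photosynthesis, dark reaction
GO:0009765 photosynthesis, light harvesting
GO:0009768 photosynthesis, light harvesting in photosystem I
GO:0009769 photosynthesis, light harvesting in photosystem II
GO:0009772 photosynthetic electron transport in photosystem II
GO:0009773 photosynthetic electron transport in photosystem I
GO:0009767 photosynthetic electron transport chain
GO:0010207 photosystem II assembly
GO:0010206 photosystem II repair
GO:0009522 photosystem I
GO:0009523 photosystem II
GO:0009538 photosystem I reaction center
GO:0009539 photosystem II reaction center
GO:0030076 light-harvesting complex
GO:0016168 chlorophyll binding
GO:0015995 chlorophyll biosynthetic process
GO:0015994 chlorophyll metabolic process
GO:0009579 thylakoid
GO:0009534 chloroplast thylakoid
GO:0009654 photosystem II oxygen evolving complex
GO:0010242 oxygen evolving activity
GO:0009055 electron transfer activity
GO:0045156 electron transporter, transferring electrons within the cyclic electron transport pathway of photosynthesis activity
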